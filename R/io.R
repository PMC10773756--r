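#' Read or write a labeled series dataset
#'
#' Two on-disk representations are supported:
#' \describe{
#'   \item{`"csv"`}{wide delimited text with mandatory header
#'     `id,label,t0,...,t{L-1}`, comma delimiter, period decimal separator;
#'     one row per sample.}
#'   \item{`"bundle"`}{a binary array bundle (RDS) holding `values`, `labels`
#'     and `class_names`; round-trips bit-exactly.}
#' }
#' Missing points in the text format are rejected by default; with
#' `na_action = "interpolate"` interior gaps are filled linearly per sample
#' (leading/trailing gaps are still an error), supporting streams with
#' sporadically missing measurements.
#'
#' @param path file path.
#' @param format `"csv"` or `"bundle"`.
#' @param na_action `"error"` (default) or `"interpolate"`.
#' @param class_names optional class names for `"csv"` (not stored there).
#' @return A [series_set()].
#' @examples
#' read_series(system.file("extdata", "example3.csv", package = "driftgate"))
#' @export
read_series <- function(path, format = c("csv", "bundle"),
                        na_action = c("error", "interpolate"),
                        class_names = NULL) {
  format <- match.arg(format)
  na_action <- match.arg(na_action)
  if (format == "bundle") {
    b <- readRDS(path)
    return(series_set(b$values, b$labels, b$class_names, b$dataset_id))
  }
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("read_series: '", path, "' has no data rows", call. = FALSE)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "id" || header[2L] != "label")
    stop("read_series: header must start with 'id,label,t0,...'", call. = FALSE)
  L <- length(header) - 2L
  rows <- strsplit(lines[-1L], ",", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != L + 2L)) {
    bad <- which(widths != L + 2L)[1L]
    stop(sprintf("read_series: ragged row %d has %d fields, expected %d",
                 bad, widths[bad], L + 2L), call. = FALSE)
  }
  lab_chr <- vapply(rows, `[[`, "", 2L)
  lab_num <- suppressWarnings(as.numeric(lab_chr))
  if (anyNA(lab_num) || any(lab_num != floor(lab_num))) {
    bad <- which(is.na(lab_num) | lab_num != floor(lab_num))[1L]
    stop(sprintf("read_series: non-integer label '%s' in row %d",
                 lab_chr[bad], bad), call. = FALSE)
  }
  vals <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(rows, `[`, -(1:2))))),
    nrow = length(rows), ncol = L, byrow = TRUE)
  if (anyNA(vals)) {
    if (na_action == "error") {
      bad <- which(rowSums(is.na(vals)) > 0L)[1L]
      stop(sprintf("read_series: missing value in row %d (use na_action = 'interpolate')",
                   bad), call. = FALSE)
    }
    vals <- t(apply(vals, 1L, fill_interior_gaps))
    if (anyNA(vals))
      stop("read_series: leading/trailing missing points cannot be interpolated",
           call. = FALSE)
  }
  series_set(vals, as.integer(lab_num), class_names,
             dataset_id = sub("\\.[^.]*$", "", basename(path)))
}

fill_interior_gaps <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) < 2L) return(x)
  out <- x
  inner <- seq(min(ok), max(ok))
  out[inner] <- approx(ok, x[ok], xout = inner)$y
  out
}

#' @rdname read_series
#' @param data a [series_set()] to write.
#' @export
write_series <- function(data, path, format = c("csv", "bundle")) {
  format <- match.arg(format)
  stopifnot(inherits(data, "series_set"))
  if (format == "bundle") {
    saveRDS(list(values = data$values, labels = data$labels,
                 class_names = data$class_names,
                 dataset_id = data$dataset_id), path)
    return(invisible(path))
  }
  L <- ncol(data$values)
  header <- paste(c("id", "label", paste0("t", seq_len(L) - 1L)),
                  collapse = ",")
  body <- vapply(seq_len(nrow(data$values)), function(i) {
    paste(c(i - 1L, data$labels[i],
            format(data$values[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)),
          collapse = ",")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
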
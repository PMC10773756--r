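#' Specify how update windows are carved from a dataset
#'
#' Two update modes cover the two stream regimes:
#' \describe{
#'   \item{`feature_update`}{for datasets with few, long, periodic samples:
#'     windows are spans of time points. With cycle wavelength `w` and
#'     multiplier `n` the window size is `w * n` and the window count N must
#'     satisfy `w * n * N <= L`; the step is typically one wavelength.}
#'   \item{`sample_update`}{for datasets with many short samples: windows are
#'     contiguous blocks of samples; the leading `train_split` samples form
#'     the training set (default `S - count * size`, i.e. trailing blocks
#'     become windows).}
#' }
#'
#' @param mode `"feature_update"` or `"sample_update"`.
#' @param size window size (points in feature mode, samples in sample mode).
#'   In feature mode may be omitted when `cycle_wavelength` and `multiplier`
#'   are given (then `size = w * n`).
#' @param step advance between consecutive windows (same unit as `size`).
#' @param count number of update windows N.
#' @param cycle_wavelength optional cycle wavelength w (feature mode).
#' @param multiplier optional multiplier n so that `size = w * n`.
#' @param train_split samples reserved for training (sample mode); default
#'   `S - count * size`.
#' @return A `window_spec` object.
#' @export
window_spec <- function(mode = c("feature_update", "sample_update"),
                        size = NULL, step = NULL, count = 1L,
                        cycle_wavelength = NULL, multiplier = NULL,
                        train_split = NULL) {
  mode <- match.arg(mode)
  if (is.null(size)) {
    if (is.null(cycle_wavelength) || is.null(multiplier))
      stop("window_spec: give size, or cycle_wavelength and multiplier",
           call. = FALSE)
    size <- cycle_wavelength * multiplier
  }
  if (is.null(step)) step <- if (!is.null(cycle_wavelength)) cycle_wavelength else size
  stopifnot(size >= 1, step >= 1, count >= 1)
  structure(list(mode = mode, size = as.integer(size), step = as.integer(step),
                 count = as.integer(count),
                 cycle_wavelength = cycle_wavelength, multiplier = multiplier,
                 train_split = train_split),
            class = "window_spec")
}

#' Split a dataset into a training block and update windows
#'
#' In feature mode the training block is columns `[0, size)` of every sample
#' and window k covers columns `[k*step, k*step + size)`; the constraint
#' `w * n * N <= L` is enforced. In sample mode the training block is the
#' leading `train_split` samples and window k is the next block of `size`
#' samples advancing by `step`; full series length is kept in every window.
#'
#' @param data a [series_set()].
#' @param spec a [window_spec()].
#' @return A list with `train` (a `series_set`), `windows` (list of
#'   `series_set`s), and `ranges` (the index span of each window, for logs).
#' @examples
#' x <- series_set(matrix(rnorm(4 * 588), 4), labels = c(0, 1, 0, 1))
#' ws <- window_spec("feature_update", cycle_wavelength = 196, multiplier = 2,
#'                   step = 196, count = 1)
#' w <- make_windows(x, ws)
#' ncol(w$train$values)  # 392
#' @export
make_windows <- function(data, spec) {
  stopifnot(inherits(data, "series_set"), inherits(spec, "window_spec"))
  if (spec$mode == "feature_update") make_feature_windows(data, spec)
  else make_sample_windows(data, spec)
}

make_feature_windows <- function(data, spec) {
  L <- ncol(data$values)
  w <- spec$cycle_wavelength
  if (!is.null(w) && !is.null(spec$multiplier)) {
    if (w * spec$multiplier * spec$count > L)
      stop(sprintf(
        "feature windows: w*n*N = %d exceeds series length L = %d",
        w * spec$multiplier * spec$count, L), call. = FALSE)
  }
  last_start <- spec$count * spec$step
  if (last_start + spec$size > L)
    stop(sprintf(
      "feature windows: window %d spans points [%d, %d) past L = %d",
      spec$count, last_start, last_start + spec$size, L), call. = FALSE)
  slice <- function(from) {
    series_set(data$values[, (from + 1L):(from + spec$size), drop = FALSE],
               data$labels, data$class_names, data$dataset_id)
  }
  starts <- spec$step * seq_len(spec$count)
  list(train = slice(0L),
       windows = lapply(starts, slice),
       ranges = lapply(starts, function(s) c(from = s, to = s + spec$size)))
}

make_sample_windows <- function(data, spec) {
  S <- nrow(data$values)
  train_split <- spec$train_split
  if (is.null(train_split)) train_split <- S - spec$count * spec$size
  need <- train_split + (spec$count - 1L) * spec$step + spec$size
  if (train_split < 0L || need > S)
    stop(sprintf(
      "sample windows: need %d samples (train %d + windows), have %d",
      need, train_split, S), call. = FALSE)
  starts <- train_split + spec$step * (seq_len(spec$count) - 1L)
  # train_split = 0 is allowed (the stream covers the whole dataset and
  # the caller supplies reference data separately)
  list(train = if (train_split > 0L)
         subset_series(data, seq_len(train_split)),
       windows = lapply(starts, function(s)
         subset_series(data, (s + 1L):(s + spec$size))),
       ranges = lapply(starts, function(s) c(from = s, to = s + spec$size)))
}
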
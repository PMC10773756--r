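#' Labeled set of fixed-length time series
#'
#' The core container of the package: an S x L numeric matrix of series
#' (rows = samples, columns = time points) plus a length-S vector of integer
#' class labels in `[0, K)` indexing into `class_names`.
#'
#' @param values numeric matrix (S x L) or an object coercible to one; no NA
#'   values are allowed (impute or reject missing points at read time).
#' @param labels integer vector of length S with class ids in `[0, K)`.
#' @param class_names character vector of K class names. Defaults to
#'   `"class_0" ... "class_{K-1}"` with K = `max(labels) + 1`.
#' @param dataset_id short string identifying the dataset.
#' @return An object of class `series_set` with fields `values`, `labels`,
#'   `class_names`, `dataset_id`.
#' @examples
#' x <- series_set(matrix(rnorm(20), 4, 5), labels = c(0, 1, 0, 1))
#' dim(x$values)
#' @export
series_set <- function(values, labels, class_names = NULL,
                       dataset_id = "dataset") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.integer(labels)
  if (is.null(class_names)) {
    k <- max(labels) + 1L
    class_names <- paste0("class_", seq_len(k) - 1L)
  }
  x <- structure(
    list(values = values, labels = labels, class_names = class_names,
         dataset_id = dataset_id),
    class = "series_set")
  validate_series_set(x)
}

validate_series_set <- function(x) {
  v <- x$values
  if (!is.matrix(v) || nrow(v) < 1L || ncol(v) < 1L)
    stop("series_set: values must be a non-empty S x L matrix", call. = FALSE)
  if (anyNA(v))
    stop("series_set: values contain NA/NaN; impute or reject at read time",
         call. = FALSE)
  if (length(x$labels) != nrow(v))
    stop("series_set: length(labels) != nrow(values)", call. = FALSE)
  if (any(x$labels < 0L) || any(x$labels >= length(x$class_names)))
    stop("series_set: labels must index class_names (0-based)", call. = FALSE)
  x
}

#' @export
print.series_set <- function(x, ...) {
  cat(sprintf("<series_set '%s'> S = %d samples, L = %d points, K = %d classes\n",
              x$dataset_id, nrow(x$values), ncol(x$values),
              length(x$class_names)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L))
  names(tab) <- x$class_names
  print(tab)
  invisible(x)
}

#' @export
dim.series_set <- function(x) dim(x$values)

# subset rows, keeping labels aligned
subset_series <- function(x, rows) {
  series_set(x$values[rows, , drop = FALSE], x$labels[rows],
             x$class_names, x$dataset_id)
}

#' Fit min-max normalization parameters
#'
#' Computes the statistics for the transform
#' `X_new = (X - X_min) / (X_max - X_min)`.
#' With scope `"per_feature_trainset"` (the default used throughout the
#' pipeline) minima and maxima are taken per column over the training set and
#' reused unchanged on every later update window, so distribution drift stays
#' visible to the drift score. With scope `"per_sample"` the statistics are
#' recomputed per row at application time and the returned object carries no
#' state.
#'
#' @param data a [series_set()].
#' @param scope `"per_feature_trainset"` or `"per_sample"`.
#' @return A `norm_params` object with fields `x_min`, `x_max`, `scope`.
#' @export
fit_normalization <- function(data,
                              scope = c("per_feature_trainset", "per_sample")) {
  scope <- match.arg(scope)
  stopifnot(inherits(data, "series_set"))
  if (scope == "per_sample") {
    p <- list(x_min = NULL, x_max = NULL, scope = scope)
  } else {
    p <- list(x_min = apply(data$values, 2L, min),
              x_max = apply(data$values, 2L, max),
              scope = scope)
  }
  structure(p, class = "norm_params")
}

minmax_rescale <- function(m, lo, hi) {
  rng <- hi - lo
  out <- sweep(sweep(m, 2L, lo, "-"), 2L, ifelse(rng > 0, rng, 1), "/")
  # degenerate range (max == min) maps to 0 by convention
  if (any(rng == 0)) out[, rng == 0] <- 0
  out
}

#' Apply (or invert) min-max normalization
#'
#' Applies `X_new = (X - X_min) / (X_max - X_min)` under the scope recorded in
#' `params`. Columns with `x_max == x_min` map to 0. Values outside the
#' training range (possible on drifted windows) pass through unclamped, so the
#' output may exceed `[0, 1]` by design.
#'
#' @param data a [series_set()].
#' @param params a `norm_params` object from [fit_normalization()].
#' @return A normalized `series_set`; labels unchanged.
#' @examples
#' x <- series_set(matrix(1:3, 1), labels = 0)
#' p <- fit_normalization(x, "per_sample")
#' normalize(x, p)$values  # 0.0 0.5 1.0
#' @export
normalize <- function(data, params) {
  stopifnot(inherits(data, "series_set"), inherits(params, "norm_params"))
  v <- data$values
  if (params$scope == "per_sample") {
    lo <- apply(v, 1L, min); hi <- apply(v, 1L, max)
    rng <- hi - lo
    out <- (v - lo) / ifelse(rng > 0, rng, 1)
    if (any(rng == 0)) out[rng == 0, ] <- 0
  } else {
    if (length(params$x_min) != ncol(v))
      stop("normalize: params fit for L = ", length(params$x_min),
           " but data has L = ", ncol(v), call. = FALSE)
    out <- minmax_rescale(v, params$x_min, params$x_max)
  }
  series_set(out, data$labels, data$class_names, data$dataset_id)
}

#' @rdname normalize
#' @export
denormalize <- function(data, params) {
  stopifnot(inherits(data, "series_set"), inherits(params, "norm_params"))
  if (params$scope != "per_feature_trainset")
    stop("denormalize requires stateful per_feature_trainset params",
         call. = FALSE)
  rng <- params$x_max - params$x_min
  v <- sweep(sweep(data$values, 2L, ifelse(rng > 0, rng, 1), "*"),
             2L, params$x_min, "+")
  series_set(v, data$labels, data$class_names, data$dataset_id)
}

#' Deterministically shuffle samples
#'
#' Permutes (row, label) pairs with a seeded RNG; the multiset of labels is
#' preserved and the same seed always yields the same permutation.
#'
#' @param data a [series_set()].
#' @param seed integer RNG seed.
#' @return A permuted `series_set`.
#' @export
shuffle_series <- function(data, seed) {
  stopifnot(inherits(data, "series_set"))
  n <- nrow(data$values)
  perm <- local_seed_sample(seed, n)
  subset_series(data, perm)
}

# sample a permutation under a private RNG state
local_seed_sample <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(n)
}
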
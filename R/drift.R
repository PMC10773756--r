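#' Fit per-feature equal-interval binning on the reference (old) dataset
#'
#' For each of the L time points (treated as L features) the minimum `Min`
#' and maximum `Max` over all old samples define the range `Delta = Max -
#' Min`, split into `n_bins` equal-width bins. The binning is frozen to the
#' old dataset: later windows are histogrammed on the same edges, with
#' out-of-range values clipped into the edge bins. A feature with
#' `Max == Min` is flagged degenerate and given a unit-width pseudo-range
#' centred on the value so its histogram stays well defined.
#'
#' @param old_data a [series_set()] (typically the normalized training set).
#' @param n_bins number of equal-width bins per feature (>= 2).
#' @param epsilon additive smoothing added to every bin count before
#'   renormalization, so that all probabilities are strictly positive and
#'   the KL divergence is always finite.
#' @return A `binning_model` with per-feature `min`, `max`, `edges`
#'   (an `(n_bins+1) x L` matrix), `n_bins`, `epsilon`, `degenerate` flags.
#' @export
fit_binning <- function(old_data, n_bins = 10L, epsilon = 0.5) {
  stopifnot(inherits(old_data, "series_set"))
  if (n_bins < 2L)
    stop("fit_binning: n_bins must be >= 2", call. = FALSE)
  lo <- apply(old_data$values, 2L, min)
  hi <- apply(old_data$values, 2L, max)
  degenerate <- hi == lo
  lo[degenerate] <- lo[degenerate] - 0.5
  hi[degenerate] <- hi[degenerate] + 0.5
  edges <- vapply(seq_along(lo),
                  function(j) seq(lo[j], hi[j], length.out = n_bins + 1L),
                  numeric(n_bins + 1L))
  structure(list(min = lo, max = hi, edges = edges,
                 n_bins = as.integer(n_bins), epsilon = epsilon,
                 degenerate = degenerate, n_features = length(lo)),
            class = "binning_model")
}

#' Per-feature binned probability distribution
#'
#' Counts each feature (column) of `data` into the model's frozen bins:
#' half-open bins `[e_i, e_{i+1})` with the last bin closed; values below
#' `Min` clip into the first bin and above `Max` into the last. Counts get
#' `epsilon` added and are renormalized to probabilities.
#'
#' @param data a [series_set()] with the model's feature count.
#' @param model a [fit_binning()] model.
#' @return A `feature_distribution`: `probs` is an `n_bins x L` matrix whose
#'   columns each sum to 1; `sample_count` the number of samples counted.
#' @export
bin_histogram <- function(data, model) {
  stopifnot(inherits(data, "series_set"), inherits(model, "binning_model"))
  if (ncol(data$values) != model$n_features)
    stop("bin_histogram: data has ", ncol(data$values),
         " features but model was fit for ", model$n_features, call. = FALSE)
  nb <- model$n_bins
  width <- (model$max - model$min) / nb
  # vectorized bin index: clip, then floor((x - min)/width), cap at nb - 1
  idx <- floor(sweep(sweep(data$values, 2L, model$min, "-"),
                     2L, width, "/"))
  idx[idx < 0] <- 0
  idx[idx > nb - 1] <- nb - 1
  probs <- vapply(seq_len(model$n_features), function(j) {
    cnt <- tabulate(idx[, j] + 1L, nbins = nb) + model$epsilon
    cnt / sum(cnt)
  }, numeric(nb))
  structure(list(probs = probs, sample_count = nrow(data$values),
                 n_bins = nb),
            class = "feature_distribution")
}

#' Kullback-Leibler divergence between two probability vectors
#'
#' `D(p || q) = sum_i p_i * ln(p_i / q_i)` in nats, with the convention
#' `0 * ln(0/q) = 0`. `q` must be strictly positive (guaranteed by the
#' epsilon smoothing in [bin_histogram()]).
#'
#' @param p,q numeric probability vectors of equal length, each summing to 1.
#' @return The divergence in nats (non-negative).
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))  # 0.1438410
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q))
    stop("kl_divergence: length mismatch", call. = FALSE)
  if (any(p < 0) || any(q < 0))
    stop("kl_divergence: negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("kl_divergence: inputs must sum to 1", call. = FALSE)
  nz <- p > 0
  if (any(q[nz] == 0))
    stop("kl_divergence: q must be positive wherever p is", call. = FALSE)
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Drift score D between old and new feature distributions
#'
#' Computes the per-feature divergences `KL(f_i_old || f_i_new)` (old
#' distribution as p, new as q) and their mean, the drift score D. The update
#' decision is `D >= threshold` (boundary inclusive).
#'
#' @param old_dist,new_dist [bin_histogram()] outputs with equal feature
#'   counts.
#' @param threshold update threshold t (optional; NA leaves `update` NA).
#' @param window_index window number recorded in the report.
#' @return A `drift_report` with `per_feature_kl`, `D`, `threshold`,
#'   `update`, `window_index`.
#' @export
drift_score <- function(old_dist, new_dist, threshold = NA_real_,
                        window_index = NA_integer_) {
  stopifnot(inherits(old_dist, "feature_distribution"),
            inherits(new_dist, "feature_distribution"))
  if (ncol(old_dist$probs) != ncol(new_dist$probs))
    stop("drift_score: feature counts differ (",
         ncol(old_dist$probs), " vs ", ncol(new_dist$probs), ")",
         call. = FALSE)
  kl <- vapply(seq_len(ncol(old_dist$probs)), function(j)
    kl_divergence(old_dist$probs[, j], new_dist$probs[, j]), 0)
  D <- mean(kl)
  structure(list(per_feature_kl = kl, D = D, threshold = threshold,
                 update = if (is.na(threshold)) NA else decide_update(D, threshold),
                 window_index = window_index),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("<drift_report> window %s: D = %.5f (t = %s) -> %s\n",
              ifelse(is.na(x$window_index), "?", x$window_index), x$D,
              ifelse(is.na(x$threshold), "-", format(x$threshold)),
              if (isTRUE(x$update)) "UPDATE" else
                if (isFALSE(x$update)) "no update" else "no decision"))
  cat(sprintf("  per-feature KL: min %.5f / mean %.5f / max %.5f (n = %d)\n",
              min(x$per_feature_kl), mean(x$per_feature_kl),
              max(x$per_feature_kl), length(x$per_feature_kl)))
  invisible(x)
}

#' Calibrate the update threshold from the null D distribution
#'
#' Bootstrap-resamples window-sized subsets of the old data, scores each
#' against a bootstrap replicate of the old distribution, and returns the
#' requested quantile of the null D values. Resampling the reference as well
#' (a double bootstrap) matters: a genuinely new clean window differs from
#' the frozen old histogram by its own sampling error *plus* the old set's,
#' and a null built against the fixed empirical reference underestimates D
#' and fires on clean windows. A threshold at the 0.95 quantile then fires
#' on roughly 5% of statistically clean windows, so drifted windows stand
#' out.
#'
#' @param old_data the reference [series_set()] (same normalization as used
#'   when scoring windows).
#' @param model the frozen [fit_binning()] model.
#' @param window_size samples per resample (match the expected window size).
#' @param quantile_level null quantile to return, in (0, 1).
#' @param n_boot number of bootstrap resamples (>= 10).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return The calibrated threshold (a single number). The null D draws are
#'   attached as attribute `"null_D"`.
#' @export
calibrate_threshold <- function(old_data, model, window_size,
                                quantile_level = 0.95, n_boot = 200L,
                                seed = 1L) {
  stopifnot(quantile_level > 0, quantile_level < 1)
  if (n_boot < 10L)
    stop("calibrate_threshold: n_boot must be >= 10", call. = FALSE)
  S <- nrow(old_data$values)
  old_rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_rs)) assign(".Random.seed", old_rs,
                                       envir = globalenv()))
  set.seed(as.integer(seed))
  null_D <- vapply(seq_len(n_boot), function(b) {
    ref_rows <- sample.int(S, S, replace = TRUE)
    win_rows <- sample.int(S, window_size, replace = TRUE)
    drift_score(bin_histogram(subset_series(old_data, ref_rows), model),
                bin_histogram(subset_series(old_data, win_rows), model))$D
  }, 0)
  # inverse-ECDF quantile so the threshold exceeds >= quantile_level of the
  # null draws by construction
  t_hat <- as.numeric(stats::quantile(null_D, quantile_level, names = FALSE,
                                      type = 1))
  attr(t_hat, "null_D") <- null_D
  t_hat
}
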
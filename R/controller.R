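#' Update decision rule
#'
#' The preprocessor fires exactly when the drift score reaches the update
#' threshold: `D >= t` (boundary inclusive).
#'
#' @param D drift score (non-negative).
#' @param t update threshold (> 0).
#' @return `TRUE` if the window must be preprocessed before classification.
#' @export
decide_update <- function(D, t) {
  stopifnot(is.finite(D), D >= -1e-12, t > 0)
  D >= t
}

#' Pipeline configuration
#'
#' Bundles every tunable of the streaming pipeline. The per-dataset
#' thresholds found by experimental exploration on the five reference
#' streams are available as [dataset_presets()]; by default the threshold is
#' calibrated from the null D distribution instead ([calibrate_threshold()]).
#'
#' @param threshold update threshold t (> 0), or `NA` to calibrate at fit
#'   time from the null quantile.
#' @param window a [window_spec()] (optional; streams can also be supplied
#'   as ready-made window lists).
#' @param n_bins,epsilon drift-histogram settings ([fit_binning()]).
#' @param preprocessor a [preprocessor_config()].
#' @param elm_hidden ELM hidden-layer width.
#' @param classifier a [classifier_config()].
#' @param normalization_scope see [fit_normalization()].
#' @param calibration_quantile,calibration_n_boot null-quantile settings
#'   used when `threshold` is `NA`.
#' @param seed master seed for fitting.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(threshold = NA_real_, window = NULL,
                            n_bins = 10L, epsilon = 0.5,
                            preprocessor = preprocessor_config(),
                            elm_hidden = 32L,
                            classifier = classifier_config(),
                            normalization_scope = "per_feature_trainset",
                            calibration_quantile = 0.95,
                            calibration_n_boot = 200L,
                            seed = 1L) {
  if (!is.na(threshold) && threshold <= 0)
    stop("pipeline_config: threshold must be > 0", call. = FALSE)
  structure(list(threshold = threshold, window = window,
                 n_bins = as.integer(n_bins), epsilon = epsilon,
                 preprocessor = preprocessor,
                 elm_hidden = as.integer(elm_hidden),
                 classifier = classifier,
                 normalization_scope = normalization_scope,
                 calibration_quantile = calibration_quantile,
                 calibration_n_boot = as.integer(calibration_n_boot),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Per-dataset configuration presets
#'
#' Window and threshold settings used on the five reference streams: the two
#' plant surface-potential sets (LIRB127: 2 classes, L = 588, cycle 196;
#' LIRB78: 3 classes, L = 1764, cycle 588; both feature-update), the ECG
#' beat set (5 classes, 5000 samples of length 140, sample-update), the
#' speech-emotion set (CASIA, 6 classes, 1305 samples) and the crop
#' remote-sensing set (24 classes, 31200 samples). Thresholds were found by
#' experimental exploration on each stream.
#'
#' @return Named list of lists with `window` ([window_spec()]) and
#'   `threshold`.
#' @export
dataset_presets <- function() {
  list(
    lirb127 = list(
      window = window_spec("feature_update", cycle_wavelength = 196L,
                           multiplier = 2L, step = 196L, count = 1L),
      threshold = 0.60),
    lirb78 = list(
      window = window_spec("feature_update", cycle_wavelength = 588L,
                           multiplier = 2L, step = 588L, count = 1L),
      threshold = 0.62),
    ecg5000 = list(
      window = window_spec("sample_update", size = 500L, step = 500L,
                           count = 5L),
      threshold = 0.73),
    casia = list(
      window = window_spec("sample_update", size = 20L, step = 20L,
                           count = 5L),
      threshold = 0.68),
    crop = list(
      window = window_spec("sample_update", size = 1200L, step = 1200L,
                           count = 5L),
      threshold = 0.76))
}

#' Fit every frozen artifact of the pipeline on the old dataset
#'
#' Fits, in order: the normalization parameters; the equal-interval binning
#' and the old-data feature distribution (on normalized data, so thresholds
#' are scale-free); the ELM autoregressive preprocessor; the stacked LSTM
#' classifier (trained once, on the shuffled normalized old data). When
#' `cfg$threshold` is `NA` the threshold is calibrated as the
#' `calibration_quantile` of the bootstrap null D distribution at
#' `window_size` samples.
#'
#' @param old_data the raw training [series_set()].
#' @param cfg a [pipeline_config()].
#' @param window_size expected update-window sample count, used only for
#'   threshold calibration (default: the training sample count).
#' @return A `drift_pipeline` holding all frozen artifacts.
#' @export
fit_pipeline <- function(old_data, cfg = pipeline_config(),
                         window_size = nrow(old_data$values)) {
  stopifnot(inherits(old_data, "series_set"),
            inherits(cfg, "pipeline_config"))
  norm <- fit_normalization(old_data, cfg$normalization_scope)
  train_n <- normalize(old_data, norm)
  binning <- fit_binning(train_n, cfg$n_bins, cfg$epsilon)
  old_dist <- bin_histogram(train_n, binning)
  threshold <- cfg$threshold
  if (is.na(threshold))
    threshold <- as.numeric(calibrate_threshold(
      train_n, binning, window_size, cfg$calibration_quantile,
      cfg$calibration_n_boot, cfg$seed))
  elm <- train_preprocessor(train_n, cfg$preprocessor, cfg$elm_hidden,
                            cfg$seed)
  clf <- train_classifier(shuffle_series(train_n, cfg$seed), cfg$classifier)
  structure(list(config = cfg, norm = norm, binning = binning,
                 old_dist = old_dist, threshold = threshold, elm = elm,
                 classifier = clf, n_classifier_fits = 1L),
            class = "drift_pipeline")
}

#' Run the model update strategy over a stream of windows
#'
#' For each window in order: normalize with the frozen training parameters;
#' compute the drift score D against the old distribution; if `D >=
#' threshold` rewrite the window with the ELM preprocessor, otherwise leave
#' it untouched; classify with the frozen LSTM; record per-window metrics
#' against the window labels. Neither the classifier nor the binning model
#' is ever refit.
#'
#' @param pipeline a [fit_pipeline()] result.
#' @param windows list of raw [series_set()] windows, consumed sequentially.
#' @param threshold override for the pipeline threshold (e.g. `Inf` gives
#'   the frozen-classifier baseline with the preprocessor disabled).
#' @param verbose print one log line per window.
#' @return A `stream_result`: `records` (per-window list with
#'   `window_index`, `drift` report, `preprocessor_fired`, `predictions`,
#'   `metrics`) and `totals` (`n_windows`, `n_updates`, `mean_acc`,
#'   `mean_auc`).
#' @export
run_stream <- function(pipeline, windows, threshold = pipeline$threshold,
                       verbose = FALSE) {
  stopifnot(inherits(pipeline, "drift_pipeline"))
  for (need in c("norm", "binning", "old_dist", "elm", "classifier"))
    if (is.null(pipeline[[need]]))
      stop("run_stream: pipeline is missing fitted artifact '", need, "'",
           call. = FALSE)
  records <- vector("list", length(windows))
  for (k in seq_along(windows)) {
    win_n <- normalize(windows[[k]], pipeline$norm)
    drift <- drift_score(pipeline$old_dist,
                         bin_histogram(win_n, pipeline$binning),
                         threshold, k)
    fired <- isTRUE(drift$update)
    if (fired)
      win_n <- preprocess_window(pipeline$elm, win_n,
                                 pipeline$config$preprocessor)
    pred <- predict(pipeline$classifier, win_n)
    metrics <- metric_report(win_n$labels, pred$labels, pred$probs,
                             length(pipeline$classifier$class_names))
    if (verbose)
      message(sprintf(
        "window %d: D = %.5f (t = %.5f) -> %s | ACC %.4f",
        k, drift$D, threshold,
        if (fired) "update" else "pass", metrics$acc))
    records[[k]] <- list(window_index = k, drift = drift,
                         preprocessor_fired = fired,
                         predictions = pred$labels, metrics = metrics)
  }
  n_upd <- sum(vapply(records, `[[`, TRUE, "preprocessor_fired"))
  accs <- vapply(records, function(r) r$metrics$acc, 0)
  aucs <- vapply(records, function(r) r$metrics$auc, 0)
  structure(list(records = records,
                 totals = list(n_windows = length(records),
                               n_updates = n_upd,
                               mean_acc = if (length(accs)) mean(accs) else NA_real_,
                               mean_auc = if (length(aucs)) mean(aucs) else NA_real_),
                 threshold = threshold),
            class = "stream_result")
}

#' @export
print.stream_result <- function(x, ...) {
  cat(sprintf("<stream_result> %d windows, %d updates (t = %.5f)\n",
              x$totals$n_windows, x$totals$n_updates, x$threshold))
  for (r in x$records)
    cat(sprintf("  win %d: D = %.5f %s ACC %.4f AUC %s\n",
                r$window_index, r$drift$D,
                if (r$preprocessor_fired) "[UPDATE]" else "[pass]  ",
                r$metrics$acc,
                ifelse(is.na(r$metrics$auc), "NA",
                       sprintf("%.4f", r$metrics$auc))))
  invisible(x)
}

#' Serialize a stream result
#'
#' `stream_to_json()` emits one JSON line per window (window index, D,
#' per-feature KL summary, threshold, update flag, metrics), the format the
#' CLI writes next to the per-window metric CSV produced by
#' `stream_metrics_frame()`.
#'
#' @param x a `stream_result`.
#' @return `stream_to_json()`: character vector of JSON lines;
#'   `stream_metrics_frame()`: a data.frame with one row per window.
#' @export
stream_to_json <- function(x) {
  stopifnot(inherits(x, "stream_result"))
  vapply(x$records, function(r) {
    kl <- r$drift$per_feature_kl
    jsonlite::toJSON(list(
      window = r$window_index,
      D = r$drift$D,
      per_feature_kl_summary = list(min = min(kl), mean = mean(kl),
                                    max = max(kl)),
      threshold = x$threshold,
      update = r$preprocessor_fired,
      metrics = list(acc = r$metrics$acc, sen = r$metrics$sen,
                     spe = r$metrics$spe, f1 = r$metrics$f1,
                     auc = r$metrics$auc)),
      auto_unbox = TRUE, digits = NA, na = "null")
  }, "")
}

#' @rdname stream_to_json
#' @export
stream_metrics_frame <- function(x) {
  stopifnot(inherits(x, "stream_result"))
  do.call(rbind, lapply(x$records, function(r)
    data.frame(window = r$window_index, D = r$drift$D,
               update = r$preprocessor_fired, acc = r$metrics$acc,
               sen = r$metrics$sen, spe = r$metrics$spe,
               f1 = r$metrics$f1, auc = r$metrics$auc,
               averaging = r$metrics$averaging)))
}
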
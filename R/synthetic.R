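#' Describe a synthetic drifting stream
#'
#' The generator emulates class-structured periodic biosignals: class k is a
#' sinusoid archetype with frequency `k + 1` cycles per series (so classes
#' are separable by temporal dynamics alone), unit base amplitude, per-sample
#' amplitude jitter and phase jitter, plus additive Gaussian base noise.
#' Each update window may additionally carry the failure modes the framework
#' targets: additive offset (concept drift), amplitude scaling, elevated
#' noise, anomalous spikes, and missing points (interior-interpolated at
#' generation time so downstream code sees complete series).
#'
#' `drift_ops()` builds one window's corruption description; the default is
#' a clean window.
#'
#' @param n_classes number of classes K.
#' @param length series length L (time points).
#' @param train_size training samples S_train.
#' @param window_size samples per update window.
#' @param windows list of [drift_ops()], one per update window.
#' @param base_noise_sd additive Gaussian noise on every sample.
#' @param amplitude_jitter_sd per-sample amplitude s.d. around 1.
#' @param phase_jitter maximum per-sample phase offset (radians, uniform in
#'   `[-phase_jitter, phase_jitter]`).
#' @param seed integer seed; generation is bit-reproducible given it.
#' @return A `drift_scenario` object.
#' @export
drift_scenario <- function(n_classes = 3L, length = 64L, train_size = 300L,
                           window_size = 150L,
                           windows = replicate(5L, drift_ops(),
                                               simplify = FALSE),
                           base_noise_sd = 0.1, amplitude_jitter_sd = 0.1,
                           phase_jitter = pi / 4, seed = 1L) {
  stopifnot(n_classes >= 2L, length >= 8L, train_size >= n_classes,
            window_size >= n_classes)
  for (w in windows) stopifnot(inherits(w, "drift_ops"))
  structure(list(n_classes = as.integer(n_classes),
                 length = as.integer(length),
                 train_size = as.integer(train_size),
                 window_size = as.integer(window_size),
                 windows = windows, base_noise_sd = base_noise_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 phase_jitter = phase_jitter, seed = as.integer(seed)),
            class = "drift_scenario")
}

#' @rdname drift_scenario
#' @param offset additive offset delta applied to the whole window.
#' @param scale multiplicative amplitude factor gamma.
#' @param extra_noise_sd s.d. of extra Gaussian noise added on top of the
#'   base noise.
#' @param spike_rate per-point probability of an anomalous spike.
#' @param spike_amp spike magnitude; `NA` means 5 x the clean-signal global
#'   standard deviation (sign random).
#' @param missing_rate per-point probability a measurement is dropped and
#'   linearly interpolated.
#' @export
drift_ops <- function(offset = 0, scale = 1, extra_noise_sd = 0,
                      spike_rate = 0, spike_amp = NA_real_,
                      missing_rate = 0) {
  stopifnot(spike_rate >= 0, spike_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            extra_noise_sd >= 0, scale > 0)
  structure(list(offset = offset, scale = scale,
                 extra_noise_sd = extra_noise_sd, spike_rate = spike_rate,
                 spike_amp = spike_amp, missing_rate = missing_rate),
            class = "drift_ops")
}

is_drifted <- function(op) {
  op$offset != 0 || op$scale != 1 || op$extra_noise_sd > 0 ||
    op$spike_rate > 0 || op$missing_rate > 0
}

#' The default acceptance scenario
#'
#' Three classes, series length 64, 300 training samples, five windows of
#' 150 samples; windows 2 and 4 carry elevated noise (s.d. 0.3) and 5%
#' anomalous spikes, the rest are clean.
#'
#' @param seed RNG seed.
#' @return A [drift_scenario()].
#' @export
default_scenario <- function(seed = 1L) {
  drifted <- drift_ops(extra_noise_sd = 0.3, spike_rate = 0.05)
  drift_scenario(
    windows = list(drift_ops(), drifted, drift_ops(), drifted, drift_ops()),
    seed = seed)
}

# clean samples for given labels: sinusoid archetypes + jitter + base noise
gen_samples <- function(sc, labels) {
  S <- length(labels); L <- sc$length
  t_idx <- seq_len(L) - 1L
  amp <- 1 + rnorm(S, 0, sc$amplitude_jitter_sd)
  phase <- runif(S, -sc$phase_jitter, sc$phase_jitter)
  freq <- labels + 1L  # cycles per series
  clean <- t(vapply(seq_len(S), function(i)
    amp[i] * sin(2 * pi * freq[i] * t_idx / L + phase[i]),
    numeric(L)))
  clean + matrix(rnorm(S * L, 0, sc$base_noise_sd), S, L)
}

apply_drift_ops <- function(values, op, signal_sd) {
  v <- op$scale * values + op$offset
  S <- nrow(v); L <- ncol(v)
  if (op$extra_noise_sd > 0)
    v <- v + matrix(rnorm(S * L, 0, op$extra_noise_sd), S, L)
  if (op$spike_rate > 0) {
    amp <- if (is.na(op$spike_amp)) 5 * signal_sd else op$spike_amp
    hit <- matrix(runif(S * L) < op$spike_rate, S, L)
    v[hit] <- v[hit] + amp * sample(c(-1, 1), sum(hit), replace = TRUE)
  }
  if (op$missing_rate > 0) {
    drop <- matrix(runif(S * L) < op$missing_rate, S, L)
    drop[, c(1L, L)] <- FALSE  # keep endpoints so interpolation is defined
    v[drop] <- NA_real_
    v <- t(apply(v, 1L, fill_interior_gaps))
  }
  v
}

#' Generate a synthetic drifting stream
#'
#' Draws the training set from clean archetypes, then each update window the
#' same way followed by its window's drift operations. Labels are balanced
#' multinomial draws over the classes. Deterministic given the scenario
#' seed.
#'
#' @param sc a [drift_scenario()].
#' @return A list: `train` (a [series_set()]), `windows` (list of
#'   `series_set`s), `truth` (logical, which windows carry nonzero drift).
#' @export
generate_scenario <- function(sc) {
  stopifnot(inherits(sc, "drift_scenario"))
  old_rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_rs)) assign(".Random.seed", old_rs,
                                       envir = globalenv()))
  set.seed(sc$seed)
  cls <- seq_len(sc$n_classes) - 1L
  draw_labels <- function(n)
    sample(rep_len(cls, n))  # balanced mix, shuffled
  train_labels <- draw_labels(sc$train_size)
  train_vals <- gen_samples(sc, train_labels)
  signal_sd <- stats::sd(as.vector(train_vals))
  train <- series_set(train_vals, train_labels, dataset_id = "synthetic_train")
  windows <- vector("list", length(sc$windows))
  for (k in seq_along(sc$windows)) {
    labels <- draw_labels(sc$window_size)
    vals <- apply_drift_ops(gen_samples(sc, labels), sc$windows[[k]],
                            signal_sd)
    windows[[k]] <- series_set(vals, labels, train$class_names,
                               dataset_id = sprintf("synthetic_win%d", k))
  }
  list(train = train, windows = windows,
       truth = vapply(sc$windows, is_drifted, TRUE))
}

#' Sweep drift magnitude against the measured drift score
#'
#' For each offset delta in `grid` and each seed, generates a one-window
#' scenario with that additive offset, runs the drift scoring path
#' (normalize, bin, score) and optionally the full pipeline, and tabulates
#' the median D per magnitude. Powers the monotonicity checks.
#'
#' @param grid numeric vector of additive offsets.
#' @param n_seeds seeds per grid point.
#' @param sc_template scenario whose sizes/noise are reused.
#' @param n_bins,epsilon binning settings.
#' @param path optional CSV path to write the table to.
#' @return A data.frame with columns `offset`, `median_D`, `n_seeds`.
#' @export
sweep_drift <- function(grid, n_seeds = 10L, sc_template = default_scenario(),
                        n_bins = 10L, epsilon = 0.5, path = NULL) {
  stopifnot(length(grid) >= 1L)
  med <- vapply(grid, function(delta) {
    Ds <- vapply(seq_len(n_seeds), function(s) {
      sc <- drift_scenario(
        n_classes = sc_template$n_classes, length = sc_template$length,
        train_size = sc_template$train_size,
        window_size = sc_template$window_size,
        windows = list(drift_ops(offset = delta)),
        base_noise_sd = sc_template$base_noise_sd,
        amplitude_jitter_sd = sc_template$amplitude_jitter_sd,
        phase_jitter = sc_template$phase_jitter, seed = s)
      g <- generate_scenario(sc)
      np <- fit_normalization(g$train)
      train_n <- normalize(g$train, np)
      bm <- fit_binning(train_n, n_bins, epsilon)
      drift_score(bin_histogram(train_n, bm),
                  bin_histogram(normalize(g$windows[[1L]], np), bm))$D
    }, 0)
    stats::median(Ds)
  }, 0)
  out <- data.frame(offset = grid, median_D = med, n_seeds = n_seeds)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
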
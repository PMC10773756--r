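test_that("fit_binning builds equal-width per-feature edges", {
  d <- series_set(matrix(c(0, 0.5, 1, 1), 4), labels = rep(0, 4))
  m <- fit_binning(d, n_bins = 2, epsilon = 0)
  expect_equal(m$edges[, 1], c(0, 0.5, 1))

  # widths equal to Delta / N within 1e-12
  d2 <- series_set(matrix(c(-1, 4, 0, 1), 2), labels = c(0, 0))
  m2 <- fit_binning(d2, n_bins = 5)
  widths <- diff(m2$edges[, 1])
  expect_equal(widths, rep(5 / 5, 5), tolerance = 1e-12)

  # degenerate feature gets a unit pseudo-range centred on the value
  dc <- series_set(matrix(3, 4, 1), labels = rep(0, 4))
  mc <- fit_binning(dc, n_bins = 4)
  expect_true(mc$degenerate[1])
  expect_equal(mc$min[1], 2.5)
  expect_equal(mc$max[1], 3.5)

  expect_error(fit_binning(d, n_bins = 1), "n_bins")
})

test_that("histograms use half-open bins, closed last bin, and clip", {
  d <- series_set(matrix(c(0, 0.5, 1, 1), 4), labels = rep(0, 4))
  m <- fit_binning(d, n_bins = 2, epsilon = 0)
  h <- bin_histogram(d, m)
  expect_equal(h$probs[, 1], c(0.25, 0.75))

  out <- series_set(matrix(c(2, -3), 2), labels = c(0, 0))
  ho <- bin_histogram(out, m)
  expect_equal(ho$probs[, 1], c(0.5, 0.5))  # one clips low, one high

  ms <- fit_binning(d, n_bins = 4, epsilon = 0.5)
  hs <- bin_histogram(d, ms)
  expect_true(all(hs$probs > 0))
  expect_equal(colSums(hs$probs), 1, ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(bin_histogram(toy_series(3, 2), m), "features")
})

test_that("kl_divergence matches the closed form and validates input", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(round(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)), 5), 0.14384)
  expect_error(kl_divergence(c(1), c(0.5, 0.5)), "length")
  expect_error(kl_divergence(c(-0.5, 1.5), c(0.5, 0.5)), "negative")
  expect_error(kl_divergence(c(0.2, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("drift score D is the mean per-feature KL with sane reports", {
  d <- toy_series(40, 6, seed = 5)
  m <- fit_binning(d)
  h <- bin_histogram(d, m)
  self <- drift_score(h, h)
  expect_identical(self$D, 0)

  # mean-of-KL arithmetic on a constructed two-feature case
  p1 <- random_prob(10, 1); q1 <- random_prob(10, 2)
  p2 <- random_prob(10, 3); q2 <- random_prob(10, 4)
  fd <- function(p, q) {
    a <- structure(list(probs = cbind(p, q), sample_count = 1, n_bins = 10),
                   class = "feature_distribution")
  }
  ds <- drift_score(fd(p1, p2), fd(q1, q2))
  expect_equal(ds$D,
               mean(c(kl_divergence(p1, q1), kl_divergence(p2, q2))),
               tolerance = 1e-12)

  # threshold decision recorded, boundary inclusive
  dec <- drift_score(h, bin_histogram(toy_series(40, 6, seed = 9), m),
                     threshold = self$D + 1)
  expect_identical(dec$update, dec$D >= self$D + 1)

  expect_error(drift_score(h, bin_histogram(toy_series(10, 4),
                                            fit_binning(toy_series(10, 4)))),
               "feature counts differ")
})

test_that("D is invariant to sample order and non-negative", {
  d <- toy_series(60, 5, seed = 8)
  m <- fit_binning(d)
  h <- bin_histogram(d, m)
  for (s in 1:5) {
    w <- toy_series(30, 5, seed = 100 + s)
    ds <- drift_score(h, bin_histogram(w, m))$D
    ds_perm <- drift_score(h, bin_histogram(shuffle_series(w, s), m))$D
    expect_identical(ds, ds_perm)
    expect_gte(ds, -1e-12)
  }
})

test_that("threshold calibration is deterministic and a true null quantile", {
  d <- toy_series(80, 6, seed = 12)
  m <- fit_binning(d)
  t1 <- calibrate_threshold(d, m, window_size = 40, n_boot = 50, seed = 4)
  t2 <- calibrate_threshold(d, m, window_size = 40, n_boot = 50, seed = 4)
  expect_identical(as.numeric(t1), as.numeric(t2))
  null_D <- attr(t1, "null_D")
  expect_gte(mean(as.numeric(t1) >= null_D), 0.95)
  expect_error(calibrate_threshold(d, m, 40, n_boot = 5), "n_boot")
})
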
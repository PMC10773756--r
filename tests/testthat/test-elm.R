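test_that("elm_init draws frozen weights with the stated shapes", {
  m <- elm_init(5, 32, 1, seed = 2)
  expect_equal(dim(m$W), c(32, 5))
  expect_length(m$b, 32)
  expect_equal(dim(m$beta), c(32, 1))
  expect_true(all(abs(m$W) <= 1) && all(abs(m$b) <= 1))
  expect_identical(elm_init(5, 32, 1, seed = 2)$W, m$W)
  expect_s3_class(elm_init(1, 1, 1), "elm_model")  # degenerate but valid
  expect_error(elm_init(0, 4, 1), ">= 1")
})

test_that("elm_forward reproduces hand-computed sigmoid arithmetic", {
  m <- elm_init(2, 2, 1, seed = 1)
  m$W <- matrix(c(0.5, -0.25, 1, 0.75), 2, 2)
  m$b <- c(0.1, -0.2)
  m$beta <- matrix(c(2, -1), 2, 1)
  x <- c(0.3, 0.6)
  h1 <- 1 / (1 + exp(-(0.5 * 0.3 + 1 * 0.6 + 0.1)))
  h2 <- 1 / (1 + exp(-(-0.25 * 0.3 + 0.75 * 0.6 - 0.2)))
  expect_equal(elm_forward(m, x)[1, 1], 2 * h1 - 1 * h2, tolerance = 1e-12)

  # beta = 0 -> zero output; batch rows equal single-row results
  z <- elm_init(3, 8, 1, seed = 3)
  X <- matrix(rnorm(6), 2, 3)
  expect_equal(elm_forward(z, X), matrix(0, 2, 1))
  m2 <- elm_fit(z, matrix(rnorm(30), 10, 3), matrix(rnorm(10)))
  batch <- elm_forward(m2, X)
  expect_equal(batch[1, ], elm_forward(m2, X[1, ])[1, ])
  expect_equal(batch[2, ], elm_forward(m2, X[2, ])[1, ])
  expect_error(elm_forward(m2, matrix(1, 1, 5)), "input width")
})

test_that("elm_fit solves least squares: pseudoinverse oracle and residual
           orthogonality on random well-conditioned problems", {
  for (rep in 1:25) {
    pr <- well_conditioned_problem(rep)
    fit <- elm_fit(pr$model, pr$X, pr$targets)
    beta_oracle <- MASS::ginv(pr$H) %*% pr$targets
    expect_equal(fit$beta, beta_oracle, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_lt(max(abs(crossprod(pr$H, pr$H %*% fit$beta - pr$targets))),
              1e-6)
    # pinv route agrees too
    fit2 <- elm_fit(pr$model, pr$X, pr$targets, method = "pinv")
    expect_equal(fit2$beta, beta_oracle, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_error(elm_fit(elm_init(2, 4, 1), matrix(1, 3, 2), matrix(1, 2, 1)),
               "rows")
})

test_that("fitting zero targets returns zero weights and leaves W, b frozen", {
  m <- elm_init(3, 6, 1, seed = 5)
  W0 <- m$W; b0 <- m$b
  fit <- elm_fit(m, matrix(rnorm(30), 10, 3), matrix(0, 10, 1))
  expect_equal(fit$beta, matrix(0, 6, 1), tolerance = 1e-12)
  expect_identical(fit$W, W0)
  expect_identical(fit$b, b0)
})

test_that("train_preprocessor learns the old-data dynamics", {
  const <- series_set(matrix(0.7, 12, 20), labels = rep(0, 12),
                      class_names = "c")
  m <- train_preprocessor(const, seed = 1)
  expect_lte(attr(m, "train_mse"), 1e-4)

  sine <- sine_series(40, 48, noise = 0.05, seed = 2)
  p <- fit_normalization(sine)
  sn <- normalize(sine, p)
  ms <- train_preprocessor(sn, seed = 2)
  # training rows = S * (L - context); MSE bounded by ~10x noise variance
  # (normalized scale shrinks the noise by the feature ranges)
  expect_lte(attr(ms, "train_mse"), 10 * 0.05^2)
  xy <- driftgate:::context_embed(sn$values, 5L)
  expect_equal(nrow(xy$X), 40 * (48 - 5))

  expect_error(train_preprocessor(toy_series(3, 4), preprocessor_config()),
               "exceed context")
})

test_that("preprocess_window preserves structure and blend = 0 is identity", {
  sine <- normalize(sine_series(30, 40, seed = 4),
                    fit_normalization(sine_series(30, 40, seed = 4)))
  m <- train_preprocessor(sine, seed = 4)
  w <- sine
  out0 <- preprocess_window(m, w, preprocessor_config(blend = 0))
  expect_identical(out0$values, w$values)
  out <- preprocess_window(m, w)
  expect_identical(dim(out$values), dim(w$values))
  expect_identical(out$labels, w$labels)
  # in-distribution stability: clean data is barely changed
  expect_lte(mean((out$values - w$values)^2),
             attr(m, "train_mse") + 1e-3)
})

test_that("the preprocessor reduces D on corrupted windows (median over seeds)", {
  base <- sine_series(120, 48, noise = 0.08, seed = 10)
  np <- fit_normalization(base)
  tr <- normalize(base, np)
  bm <- fit_binning(tr)
  od <- bin_histogram(tr, bm)
  cfg <- preprocessor_config()
  elm <- train_preprocessor(tr, cfg, seed = 10)
  sig <- stats::sd(base$values)
  delta <- vapply(1:6, function(s) {
    set.seed(1000 + s)
    v <- base$values
    v <- v + matrix(rnorm(length(v), 0, 0.3), nrow(v))
    hit <- matrix(runif(length(v)) < 0.05, nrow(v))
    v[hit] <- v[hit] + 5 * sig * sample(c(-1, 1), sum(hit), replace = TRUE)
    w <- normalize(series_set(v, base$labels), np)
    drift_score(od, bin_histogram(preprocess_window(elm, w, cfg), bm))$D -
      drift_score(od, bin_histogram(w, bm))$D
  }, 0)
  expect_lt(median(delta), 0)
})

test_that("the train -> preprocess path is reproducible under a fixed seed", {
  sine <- normalize(sine_series(25, 32, seed = 6),
                    fit_normalization(sine_series(25, 32, seed = 6)))
  run <- function() {
    m <- train_preprocessor(sine, seed = 9)
    preprocess_window(m, sine)$values
  }
  expect_identical(run(), run())
})
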
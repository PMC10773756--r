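test_that("decide_update is boundary-inclusive", {
  expect_false(decide_update(0, 0.5))
  expect_true(decide_update(0.5, 0.5))
  expect_true(decide_update(0.61, 0.60))
  expect_false(decide_update(0.59, 0.60))
  expect_error(decide_update(-1, 0.5))
})

# a small fitted pipeline reused across blocks
small_pipeline <- function(seed = 1L) {
  g <- generate_scenario(drift_scenario(
    n_classes = 2L, length = 24L, train_size = 60L, window_size = 40L,
    windows = list(drift_ops(), drift_ops(offset = 0.6), drift_ops(),
                   drift_ops(offset = 0.6)),
    seed = seed))
  cfg <- pipeline_config(
    classifier = classifier_config(units = 6L, epochs = 8L, seed = seed),
    seed = seed)
  list(g = g, pipe = fit_pipeline(g$train, cfg, window_size = 40L))
}

test_that("the update strategy fires exactly where D crosses t", {
  sp <- small_pipeline(3L)
  res <- run_stream(sp$pipe, sp$g$windows)
  fired <- vapply(res$records, `[[`, TRUE, "preprocessor_fired")
  Ds <- vapply(res$records, function(r) r$drift$D, 0)
  expect_identical(fired, Ds >= res$threshold)
  expect_identical(res$totals$n_updates, sum(Ds >= res$threshold))
  # offset windows (2, 4) fire, clean windows (1, 3) do not
  expect_identical(fired, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(res$totals$n_windows, 4L)
})

test_that("the classifier is fitted exactly once and never refit", {
  sp <- small_pipeline(5L)
  params_before <- sp$pipe$classifier$params
  res <- run_stream(sp$pipe, sp$g$windows)
  expect_identical(sp$pipe$classifier$params, params_before)
  expect_identical(sp$pipe$n_classifier_fits, 1L)
})

test_that("blend = 0 reduces the pipeline to the frozen baseline", {
  sp <- small_pipeline(7L)
  pipe0 <- sp$pipe
  pipe0$config$preprocessor <- preprocessor_config(blend = 0)
  res0 <- run_stream(pipe0, sp$g$windows)
  base <- run_stream(sp$pipe, sp$g$windows, threshold = Inf)
  expect_identical(lapply(res0$records, `[[`, "predictions"),
                   lapply(base$records, `[[`, "predictions"))
})

test_that("an empty stream yields an empty result and missing artifacts
           are reported", {
  sp <- small_pipeline(9L)
  empty <- run_stream(sp$pipe, list())
  expect_equal(empty$totals$n_windows, 0L)
  expect_length(empty$records, 0L)
  broken <- sp$pipe
  broken$elm <- NULL
  expect_error(run_stream(broken, sp$g$windows), "'elm'")
})

test_that("stream results serialize to JSON lines and a metric frame", {
  sp <- small_pipeline(11L)
  res <- run_stream(sp$pipe, sp$g$windows)
  js <- stream_to_json(res)
  expect_length(js, 4L)
  rec <- jsonlite::fromJSON(js[2])
  expect_identical(rec$window, 2L)
  expect_true(is.numeric(rec$D) && is.logical(rec$update))
  df <- stream_metrics_frame(res)
  expect_identical(nrow(df), 4L)
  expect_true(all(c("window", "D", "update", "acc", "auc") %in% names(df)))
})

test_that("per-dataset presets carry the published settings", {
  ps <- dataset_presets()
  expect_equal(vapply(ps, `[[`, 0, "threshold"),
               c(lirb127 = 0.60, lirb78 = 0.62, ecg5000 = 0.73,
                 casia = 0.68, crop = 0.76))
  expect_equal(ps$lirb127$window$size, 392L)
  expect_equal(ps$ecg5000$window$count, 5L)
})

test_that("the CLI train/stream/simulate/report round-trip works", {
  dir <- withr::local_tempdir()
  sim <- drift_cli(c("simulate", file.path(dir, "sim"), "4"))
  expect_true(file.exists(file.path(dir, "sim", "train.csv")))
  cfgfile <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(classifier = list(units = 4, epochs = 2),
                            seed = 4),
                       cfgfile, auto_unbox = TRUE)
  # small training file from the simulated scenario
  train <- read_series(file.path(dir, "sim", "train.csv"))
  sub <- series_set(train$values[1:60, ], train$labels[1:60],
                    train$class_names)
  write_series(sub, file.path(dir, "small.csv"))
  suppressMessages(
    drift_cli(c("train", file.path(dir, "small.csv"), cfgfile,
                file.path(dir, "run"))))
  expect_true(file.exists(file.path(dir, "run_pipeline.rds")))
  expect_true(file.exists(file.path(dir, "run_config.json")))
  # attach the simulated windows and stream them
  st <- readRDS(file.path(dir, "run_pipeline.rds"))
  st$windows <- lapply(1:2, function(k)
    read_series(file.path(dir, "sim", sprintf("window_%d.csv", k)),
                class_names = train$class_names))
  saveRDS(st, file.path(dir, "run_pipeline.rds"))
  suppressMessages(drift_cli(c("stream", file.path(dir, "run"))))
  expect_true(file.exists(file.path(dir, "run_stream.jsonl")))
  out <- utils::capture.output(df <- drift_cli(c("report",
                                                 file.path(dir, "run"))))
  expect_identical(nrow(df), 2L)
})
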
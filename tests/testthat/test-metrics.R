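test_that("one-vs-rest confusion counts tabulate correctly", {
  true <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  cc <- confusion_counts(true, pred, 2)
  # class 1 as positive: TP 3, FN 2, FP 1, TN 4
  expect_equal(cc$tp[2], 3L)
  expect_equal(cc$fn[2], 2L)
  expect_equal(cc$fp[2], 1L)
  expect_equal(cc$tn[2], 4L)
  expect_true(all(cc$tp + cc$tn + cc$fp + cc$fn == cc$total))
  expect_equal(sum(cc$tp), sum(true == pred))

  perm <- sample(10)
  cc2 <- confusion_counts(true[perm], pred[perm], 2)
  expect_identical(cc2, cc)

  perfect <- confusion_counts(0:2, 0:2, 3)
  expect_true(all(perfect$fp == 0L) && all(perfect$fn == 0L))
  expect_error(confusion_counts(c(0, 3), c(0, 1), 2), "outside")
  expect_error(confusion_counts(c(0, 1), c(0), 2), "length")
})

test_that("binary kernel reproduces the hand-tabulated toy", {
  m <- binary_metrics(tp = 3, tn = 4, fp = 1, fn = 2)
  expect_equal(unname(m["acc"]), 0.7)
  expect_equal(unname(m["sen"]), 0.6)
  expect_equal(unname(m["spe"]), 0.8)
  expect_equal(unname(m["f1"]), 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(round(unname(m["f1"]), 5), 0.66667)
  # zero-denominator rule
  expect_equal(unname(binary_metrics(0, 5, 0, 0)[c("sen", "f1")]), c(0, 0))
})

test_that("micro-OVR sensitivity is identically accuracy", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    n <- 50
    true <- sample(0:(k - 1), n, replace = TRUE)
    pred <- sample(0:(k - 1), n, replace = TRUE)
    cc <- confusion_counts(true, pred, k)
    m <- acc_sen_spe_f1(cc, "micro_ovr")
    expect_equal(unname(m["sen"]), unname(m["acc"]), tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1))
    mm <- acc_sen_spe_f1(cc, "macro_ovr")
    expect_true(all(mm >= 0 & mm <= 1))
  }
  allcorrect <- acc_sen_spe_f1(confusion_counts(0:3, 0:3, 4))
  expect_equal(unname(allcorrect), c(1, 1, 1, 1))
})

test_that("rank AUC matches Eq form, tie rule, and the exhaustive oracle", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.7, 0.6), c(TRUE, TRUE, FALSE, FALSE)),
               1.0)
  expect_equal(auc_rank(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE,
                                       FALSE)), 0.5)
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding makes ties likely
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(auc_rank(scores, pos), oracle_auc(scores, pos),
                 tolerance = 1e-12)
    # invariance under strictly monotone transform
    expect_equal(auc_rank(exp(3 * scores), pos), auc_rank(scores, pos),
                 tolerance = 1e-12)
  }
  expect_error(auc_rank(c(1, 2), c(TRUE, TRUE)), "positive and one negative")
})

test_that("multiclass AUC aggregates one-vs-rest columns", {
  # perfectly separated 3-class probabilities
  true <- c(0, 0, 1, 1, 2, 2)
  probs <- one_hot(true, 3) * 0.9 + 0.05
  probs <- probs / rowSums(probs)
  expect_equal(multiclass_auc(probs, true), 1.0)

  # binary case reduces to auc_rank on the positive column
  set.seed(5)
  p2 <- matrix(runif(20), 10); p2 <- p2 / rowSums(p2)
  t2 <- sample(0:1, 10, replace = TRUE)
  expect_equal(multiclass_auc(p2, t2),
               mean(c(auc_rank(p2[, 1], t2 == 0),
                      auc_rank(p2[, 2], t2 == 1))), tolerance = 1e-12)
  # complementing the scores and swapping the positive class leaves AUC
  # unchanged (two-column softmax symmetry)
  expect_equal(auc_rank(p2[, 2], t2 == 1), auc_rank(p2[, 1], t2 == 0),
               tolerance = 1e-12)

  # per-class brute force on random 3-class data
  for (rep in 1:10) {
    p3 <- matrix(runif(45), 15); p3 <- p3 / rowSums(p3)
    t3 <- sample(0:2, 15, replace = TRUE)
    if (length(unique(t3)) < 3) next
    brute <- mean(vapply(0:2, function(k)
      oracle_auc(p3[, k + 1], t3 == k), 0))
    expect_equal(multiclass_auc(p3, t3), brute, tolerance = 1e-12)
  }

  expect_warning(multiclass_auc(p2, c(rep(0, 9), 1) * 0 + c(rep(0, 9), 1),
                                "macro"), NA)
  p4 <- matrix(runif(30), 10, 3); p4 <- p4 / rowSums(p4)
  expect_warning(multiclass_auc(p4, sample(0:1, 10, replace = TRUE)),
                 "absent")
  expect_error(multiclass_auc(p4, rep(1, 10)), ">= 2 classes")
})

test_that("metric_report bundles everything consistently", {
  true <- c(0, 0, 1, 1, 2, 2)
  pred <- c(0, 0, 1, 2, 2, 2)
  probs <- one_hot(pred, 3) * 0.8 + 0.1 / 3
  probs <- probs / rowSums(probs)
  r <- metric_report(true, pred, probs, 3)
  expect_s3_class(r, "metric_report")
  expect_equal(r$acc, 5 / 6)
  expect_true(r$auc > 0 && r$auc <= 1)
  expect_true(is.na(metric_report(c(0, 0), c(0, 1), n_classes = 2)$auc))
})
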
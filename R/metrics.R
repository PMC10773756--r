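#' One-vs-rest confusion counts
#'
#' Tabulates per-class TP, TN, FP, FN treating each class in turn as
#' positive. For every class `TP + TN + FP + FN` equals the sample count and
#' the TP total across classes equals the number of correct predictions.
#'
#' @param true_labels,pred_labels integer labels in `[0, n_classes)`.
#' @param n_classes number of classes K.
#' @return A `confusion_counts` object: per-class integer vectors `tp`,
#'   `tn`, `fp`, `fn` and `total`.
#' @export
confusion_counts <- function(true_labels, pred_labels, n_classes) {
  if (length(true_labels) != length(pred_labels))
    stop("confusion_counts: label vectors differ in length", call. = FALSE)
  if (any(true_labels < 0L | true_labels >= n_classes) ||
      any(pred_labels < 0L | pred_labels >= n_classes))
    stop("confusion_counts: label outside [0, n_classes)", call. = FALSE)
  n <- length(true_labels)
  cls <- seq_len(n_classes) - 1L
  tp <- vapply(cls, function(k) sum(true_labels == k & pred_labels == k), 0L)
  fp <- vapply(cls, function(k) sum(true_labels != k & pred_labels == k), 0L)
  fn <- vapply(cls, function(k) sum(true_labels == k & pred_labels != k), 0L)
  tn <- n - tp - fp - fn
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, total = n,
                 n_classes = as.integer(n_classes)),
            class = "confusion_counts")
}

safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

#' Accuracy, sensitivity, specificity and F1 from one set of counts
#'
#' The binary kernel of the one-vs-rest metrics:
#' ACC = (TP+TN)/(TP+TN+FP+FN), SEN = TP/(TP+FN), SPE = TN/(FP+TN),
#' F1 = 2 * precision * recall / (precision + recall), with any
#' zero-denominator term defined as 0.
#'
#' @param tp,tn,fp,fn non-negative counts (scalars or aligned vectors).
#' @return Named numeric vector (or matrix) with `acc`, `sen`, `spe`, `f1`.
#' @examples
#' binary_metrics(tp = 3, tn = 4, fp = 1, fn = 2)
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  prec <- safe_div(tp, tp + fp)
  sen <- safe_div(tp, tp + fn)
  c(acc = safe_div(tp + tn, tp + tn + fp + fn),
    sen = sen,
    spe = safe_div(tn, fp + tn),
    f1 = safe_div(2 * prec * sen, prec + sen))
}

#' Accuracy, sensitivity, specificity and F1 from confusion counts
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN), SEN = TP/(TP+FN), SPE = TN/(FP+TN),
#' F1 = 2 * precision * recall / (precision + recall). `"micro_ovr"` pools
#' the one-vs-rest counts across classes before applying the formulas (for
#' which SEN is identically the plain multiclass accuracy); `"macro_ovr"`
#' averages the per-class values. Zero-denominator terms are defined as 0.
#'
#' @param counts a [confusion_counts()] object.
#' @param averaging `"micro_ovr"` (default) or `"macro_ovr"`.
#' @return Named numeric vector `c(acc, sen, spe, f1)`, all in `[0, 1]`.
#' @export
acc_sen_spe_f1 <- function(counts, averaging = c("micro_ovr", "macro_ovr")) {
  stopifnot(inherits(counts, "confusion_counts"))
  averaging <- match.arg(averaging)
  acc <- sum(counts$tp) / counts$total   # plain multiclass accuracy
  if (averaging == "micro_ovr") {
    m <- binary_metrics(sum(counts$tp), sum(counts$tn),
                        sum(counts$fp), sum(counts$fn))
  } else {
    per_class <- mapply(binary_metrics, counts$tp, counts$tn,
                        counts$fp, counts$fn)
    m <- rowMeans(per_class)
  }
  c(acc = acc, sen = unname(m["sen"]), spe = unname(m["spe"]),
    f1 = unname(m["f1"]))
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' `AUC = (sum of positive ranks - M(1+M)/2) / (M*N)` with M positives and N
#' negatives, ascending ranks, average ranks on ties: the probability that a
#' positive sample outscores a negative one.
#'
#' @param scores numeric scores (higher = more positive).
#' @param is_positive logical vector, same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_rank(c(0.9, 0.8, 0.7, 0.6), c(TRUE, TRUE, FALSE, FALSE))  # 1
#' @export
auc_rank <- function(scores, is_positive) {
  if (length(scores) != length(is_positive))
    stop("auc_rank: length mismatch", call. = FALSE)
  M <- sum(is_positive); N <- sum(!is_positive)
  if (M == 0L || N == 0L)
    stop("auc_rank: need at least one positive and one negative",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - M * (1 + M) / 2) / (M * N)
}

#' One-vs-rest multiclass AUC
#'
#' Applies [auc_rank()] per class on that class's probability column
#' (class k positive vs rest) and aggregates: `"macro"` (default) averages
#' per-class AUCs; `"micro"` pools all (score, indicator) pairs into one
#' rank computation. Classes absent from `true_labels` are skipped with a
#' warning.
#'
#' @param prob_matrix samples x classes probability matrix (rows sum to 1).
#' @param true_labels integer labels in `[0, ncol)`.
#' @param averaging `"macro"` or `"micro"`.
#' @return AUC in `[0, 1]`.
#' @export
multiclass_auc <- function(prob_matrix, true_labels,
                           averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  prob_matrix <- as.matrix(prob_matrix)
  K <- ncol(prob_matrix)
  present <- sort(unique(true_labels))
  if (length(present) < 2L)
    stop("multiclass_auc: need >= 2 classes present", call. = FALSE)
  absent <- setdiff(seq_len(K) - 1L, present)
  if (length(absent))
    warning("multiclass_auc: skipping absent class(es) ",
            paste(absent, collapse = ", "))
  if (averaging == "micro") {
    sc <- as.vector(prob_matrix[, present + 1L])
    pos <- as.vector(vapply(present, function(k) true_labels == k,
                            logical(length(true_labels))))
    return(auc_rank(sc, pos))
  }
  mean(vapply(present, function(k)
    auc_rank(prob_matrix[, k + 1L], true_labels == k), 0))
}

#' Full metric report for one prediction batch
#'
#' @param true_labels integer labels.
#' @param pred_labels predicted integer labels.
#' @param prob_matrix optional probability matrix for AUC.
#' @param n_classes number of classes.
#' @param averaging averaging scheme for [acc_sen_spe_f1()].
#' @return A `metric_report`: `acc`, `sen`, `spe`, `f1`, `auc` (NA when no
#'   probabilities given or only one class present), plus the averaging used.
#' @export
metric_report <- function(true_labels, pred_labels, prob_matrix = NULL,
                          n_classes = max(true_labels, pred_labels) + 1L,
                          averaging = "micro_ovr") {
  counts <- confusion_counts(true_labels, pred_labels, n_classes)
  m <- acc_sen_spe_f1(counts, averaging)
  auc <- NA_real_
  if (!is.null(prob_matrix) && length(unique(true_labels)) >= 2L)
    auc <- suppressWarnings(multiclass_auc(prob_matrix, true_labels))
  structure(list(acc = unname(m["acc"]), sen = unname(m["sen"]),
                 spe = unname(m["spe"]), f1 = unname(m["f1"]),
                 auc = auc, averaging = averaging, counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report %s> ACC %.4f  SEN %.4f  SPE %.4f  F1 %.4f  AUC %s\n",
    x$averaging, x$acc, x$sen, x$spe, x$f1,
    ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}
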
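#' Area under the ROC curve by midranks
#'
#' Equals the probability that a random positive outscores a random negative,
#' with ties given half credit: computed from midranks as
#' `(sum of positive ranks - n_pos(n_pos+1)/2) / (n_pos * n_neg)`, which
#' matches exhaustive pair counting exactly.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric score vector, higher = more positive.
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
#' @export
roc_auc <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  if (length(labels) != length(scores) || anyNA(scores)) {
    abort_arg("`scores` must match `labels` in length and contain no missing values.")
  }
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    abort_metric("ROC AUC is undefined when only one class is present.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Average precision of a ranking
#'
#' The weighted mean of precisions achieved at each threshold, with the
#' increase in recall from the previous threshold as the weight:
#' `AP = sum_n (R_n - R_{n-1}) P_n` over the distinct scores in descending
#' order. No trapezoidal interpolation is applied. A constant scorer's AP
#' equals the prevalence of the positive class.
#'
#' @inheritParams roc_auc
#' @return AP in (0, 1].
#' @examples
#' average_precision(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 5/6
#' @export
average_precision <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  if (length(labels) != length(scores) || anyNA(scores)) {
    abort_arg("`scores` must match `labels` in length and contain no missing values.")
  }
  npos <- sum(labels == 1L)
  if (npos == 0L) abort_metric("average precision is undefined with no positives.")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(1L - lab)
  # collapse tied scores: metrics are defined at distinct thresholds
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / npos
  sum(diff(c(0, recall)) * precision)
}

#' Threshold-based classification metrics
#'
#' Classifies as positive when the score is strictly greater than the
#' threshold, and reads accuracy, balanced accuracy, sensitivity and
#' specificity off the resulting 2x2 table. Balanced accuracy is the mean of
#' sensitivity and specificity.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold (default 0.5; strict `>`).
#' @return Named numeric vector `(accuracy, balanced_accuracy, sensitivity,
#'   specificity)`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- check_binary_labels(labels)
  if (!length(labels)) abort_arg("empty input.")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  sens <- if (npos) tp / npos else NA_real_
  spec <- if (nneg) tn / nneg else NA_real_
  c(accuracy = (tp + tn) / length(labels),
    balanced_accuracy = mean(c(sens, spec)),
    sensitivity = sens, specificity = spec)
}

#' One-row metric report for a scored data set
#'
#' @inheritParams confusion_metrics
#' @return A one-row tibble: ROC AUC, average precision, accuracy, balanced
#'   accuracy, sensitivity, specificity, threshold, number of observations
#'   and positive prevalence.
#' @export
metric_report <- function(labels, scores, threshold = 0.5) {
  cm <- confusion_metrics(labels, scores, threshold)
  tibble::tibble(
    roc_auc = roc_auc(labels, scores),
    average_precision = average_precision(labels, scores),
    accuracy = cm[["accuracy"]],
    balanced_accuracy = cm[["balanced_accuracy"]],
    sensitivity = cm[["sensitivity"]],
    specificity = cm[["specificity"]],
    threshold = threshold,
    n = length(labels),
    prevalence = mean(labels)
  )
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble of `(threshold, fpr, tpr)` at every distinct score.
#' @export
roc_curve <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab)[keep]; fp <- cumsum(1L - lab)[keep]
  tibble::tibble(threshold = c(Inf, sc[keep]),
                 fpr = c(0, fp / max(sum(labels == 0L), 1L)),
                 tpr = c(0, tp / max(sum(labels == 1L), 1L)))
}

#' Precision-recall curve points
#'
#' @inheritParams roc_auc
#' @return Tibble of `(threshold, recall, precision)` at every distinct score.
#' @export
pr_curve <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab)[keep]; fp <- cumsum(1L - lab)[keep]
  tibble::tibble(threshold = sc[keep],
                 recall = tp / max(sum(labels == 1L), 1L),
                 precision = tp / (tp + fp))
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of comparisons `m` and caps at 1.
#' `m` may exceed the number of p-values supplied (e.g. comparisons spread
#' over several cohorts).
#'
#' @param pvals Numeric p-values in [0, 1].
#' @param m Number of comparisons (defaults to `length(pvals)`).
#' @return Adjusted p-values, order preserved.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    abort_arg("p-values must lie in [0, 1].")
  }
  if (m < length(pvals)) abort_arg("`m` must be at least the number of p-values.")
  pmin(1, m * pvals)
}
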
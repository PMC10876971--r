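# Evaluation metrics for the heavily imbalanced cargo-gene task. auPRC uses
# the step-wise average-precision convention (no trapezoidal interpolation of
# the PR curve, which overestimates under imbalance); ties are grouped by
# threshold. auROC is the Mann-Whitney concordance probability with ties
# counted one half.

check_binary_labels <- function(labels, scores) {
  if (length(labels) != length(scores))
    stopf("labels and scores differ in length (%d vs %d)",
          length(labels), length(scores))
  if (anyNA(labels) || anyNA(scores)) stopf("labels/scores contain NA")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  if (all(labels == 1) || all(labels == 0))
    stopf("both classes must be present")
  invisible(NULL)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise average precision: with predictions sorted by decreasing score
#' and tied scores processed as one threshold group, AP is the sum over
#' threshold groups of (recall increment) x (precision at that threshold).
#' When all scores are tied this reduces to the class prevalence.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector, higher = more positive.
#' @return auPRC in \[0, 1\].
#' @export
average_precision <- function(labels, scores) {
  check_binary_labels(labels, scores)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  grp_end <- cumsum(rle(sc)$lengths)   # last index of each threshold group
  tp <- cumsum(lab)[grp_end]
  n_at <- grp_end
  precision <- tp / n_at
  d_tp <- diff(c(0, tp))
  sum(precision * d_tp) / sum(lab)
}

#' Area under the ROC curve
#'
#' Equals the Mann-Whitney concordance probability: the chance that a random
#' positive outscores a random negative, ties counted 1/2 (computed via
#' average ranks).
#'
#' @inheritParams average_precision
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  check_binary_labels(labels, scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)   # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-table metrics at a score cutoff
#'
#' Predicted positive means `score >= cutoff`. With no predicted positives,
#' precision is reported as `NA` (and a message emitted) rather than 0/0.
#'
#' @inheritParams average_precision
#' @param cutoff decision threshold.
#' @return named list `precision`, `sensitivity`, `specificity`.
#' @export
threshold_metrics <- function(labels, scores, cutoff) {
  check_binary_labels(labels, scores)
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  precision <- if (tp + fp == 0) {
    message("no predicted positives at cutoff ", cutoff, "; precision undefined")
    NA_real_
  } else tp / (tp + fp)
  list(precision = precision,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}
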
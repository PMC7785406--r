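#' Rank-based ROC AUC for an ordinal marker
#'
#' The area under the ROC curve computed by the Mann-Whitney identity:
#' `AUC = P(score_pos > score_neg) + 0.5 * P(score_pos == score_neg)`,
#' evaluated via midranks. Higher scores must indicate the positive
#' (hospitalized) class.
#'
#' @param scores Numeric (typically ordinal) marker values.
#' @param labels Binary labels (0/1 or logical), same length as `scores`;
#'   both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 4, 5), c(0, 0, 1, 1)) # 1
#' roc_auc(c(2, 3, 2, 1), c(1, 1, 0, 0)) # 0.875
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("`labels` must be binary (0/1) without missing values",
         call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores) # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion metrics of a "score at least cutoff" rule
#'
#' Classifies a patient positive when the score is greater than or equal
#' to the cutoff and returns sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and the Youden index `sensitivity + specificity - 1`.
#'
#' @inheritParams roc_auc
#' @param cutoff Severity cutoff, normally in `{2, ..., 5}` for a 1-5
#'   Likert score.
#' @return List with `sensitivity`, `specificity`, `youden` and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion_at_cutoff(c(4, 5, 3, 1, 2, 4), c(1, 1, 1, 0, 0, 0), 3)
confusion_at_cutoff <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  check_scalar_number(cutoff, "cutoff")
  if (!all(labels %in% c(0L, 1L)) || sum(labels) == 0L ||
      sum(labels) == length(labels)) {
    stop("`labels` must be binary with both classes present", call. = FALSE)
  }
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1L)
  fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L)
  fp <- sum(pred & labels == 0L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       youden = sens + spec - 1,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Metrics of a binary decision rule from its operating point
#'
#' For a rule that outputs a single yes/no prediction the ROC curve has
#' one interior vertex, so the Youden index is `sens + spec - 1` and the
#' AUC collapses to `(sens + spec) / 2`.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @return List with `youden` and `auc`.
#' @export
#' @examples
#' binary_rule_metrics(0.81, 0.73) # youden 0.54, auc 0.77
binary_rule_metrics <- function(sensitivity, specificity) {
  check_scalar_number(sensitivity, "sensitivity")
  check_scalar_number(specificity, "specificity")
  list(youden = sensitivity + specificity - 1,
       auc = (sensitivity + specificity) / 2)
}
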
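# Performance evaluation: confusion-based scores, ROC / precision-recall
# curves with trapezoidal areas, and Bland-Altman limits of agreement for
# per-night count comparisons.

#' Confusion counts from predicted and true binary labels
#'
#' @param predicted,truth 0/1 vectors (1 = positive class).
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  structure(list(
    tp = sum(predicted == 1L & truth == 1L),
    fp = sum(predicted == 1L & truth == 0L),
    fn = sum(predicted == 0L & truth == 1L),
    tn = sum(predicted == 0L & truth == 0L)
  ), class = "confusion_counts")
}

#' Standard metrics of a binary confusion table
#'
#' Sensitivity (true positive rate), specificity (true negative rate),
#' accuracy, Matthews correlation coefficient, positive and negative
#' predictive value. A metric whose denominator is zero is reported as `NA`
#' (undefined), never silently as 0.
#'
#' @param c A `confusion_counts` or a list/vector with `tp`, `fp`, `fn`, `tn`.
#' @return Named list of the six metrics.
#' @export
confusion_metrics <- function(c) {
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  fn <- as.numeric(c$fn); tn <- as.numeric(c$tn)
  if (min(tp, fp, fn, tn) < 0 || tp + fp + fn + tn < 1) {
    stopf("confusion counts must be nonnegative with at least one observation")
  }
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_,
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn)
  )
}

#' ROC and precision-recall curves with trapezoidal areas
#'
#' Curves are traced over all distinct score thresholds (ties grouped). The
#' precision-recall baseline of a random classifier is the positive-class
#' prevalence.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `roc` (data frame `fpr`, `tpr`), `roc_auc`, `pr` (data
#'   frame `recall`, `precision`), `pr_auc`, and `baseline` (prevalence).
#' @export
roc_pr_curves <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stopf("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # cumulative counts at each distinct threshold (score >= s)
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1L - y)[keep]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  roc_auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)

  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  recall <- c(0, recall)
  precision <- c(precision[1], precision)
  pr_auc <- sum(diff(recall) * (head(precision, -1) + tail(precision, -1)) / 2)

  list(roc = data.frame(fpr = fpr, tpr = tpr), roc_auc = roc_auc,
       pr = data.frame(recall = recall, precision = precision), pr_auc = pr_auc,
       baseline = n_pos / (n_pos + n_neg))
}

#' Bland-Altman agreement between automated and annotated counts
#'
#' Differences are `automated - annotated` per night; the limits of
#' agreement are `mean(d) +/- 1.96 * SD(d)` (sample standard deviation).
#'
#' @param records Data frame with columns `automated_count` and
#'   `annotated_count` (one row per night); at least 2 rows.
#' @return List with `mean_diff`, `lower_limit`, `upper_limit`, `sd_diff`,
#'   and the per-night `differences`.
#' @export
bland_altman <- function(records) {
  if (nrow(records) < 2L) stopf("need at least 2 nights for Bland-Altman limits")
  if (any(records$automated_count < 0 | records$annotated_count < 0)) {
    stopf("counts must be nonnegative")
  }
  d <- records$automated_count - records$annotated_count
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, lower_limit = m - 1.96 * s, upper_limit = m + 1.96 * s,
       sd_diff = s, differences = d)
}
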
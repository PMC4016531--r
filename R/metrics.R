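#' Confusion counts
#'
#' @param tp,fp,tn,fn nonnegative integer counts of true positive, false
#'   positive, true negative and false negative examples
#' @return object of class `confusion_counts`
#' @export
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth vectors of -1/+1 labels
#' @return a [confusion_counts]
#' @export
count_confusion <- function(predicted, truth) {
  confusion_counts(tp = sum(predicted == 1 & truth == 1),
                   fp = sum(predicted == 1 & truth == -1),
                   tn = sum(predicted == -1 & truth == -1),
                   fn = sum(predicted == -1 & truth == 1))
}

#' Accuracy, precision, recall and F-measure from confusion counts
#'
#' accuracy = (TP + TN) / (TP + TN + FP + FN), precision = TP / (TP + FP),
#' recall = TP / (TP + FN), F-measure = harmonic mean of precision and
#' recall. A metric with a zero denominator is defined as 0 (so an
#' all-negative prediction yields precision, recall and F of 0 rather than
#' an undefined value).
#'
#' @param counts a [confusion_counts] object (or list with fields
#'   `tp`, `fp`, `tn`, `fn`)
#' @return named numeric vector: `accuracy`, `precision`, `recall`,
#'   `f_measure`
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated examples: all confusion counts are 0")
  ratio0 <- function(num, den) if (den > 0) num / den else 0
  precision <- ratio0(tp, tp + fp)
  recall <- ratio0(tp, tp + fn)
  c(accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f_measure = ratio0(2 * precision * recall, precision + recall))
}
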
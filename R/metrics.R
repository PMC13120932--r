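#' Confusion matrix for the Normal vs. OSCC binary task
#'
#' Counts are defined with OSCC as the positive class: `tp` is the number of
#' OSCC samples predicted OSCC, `tn` the number of Normal samples predicted
#' Normal, `fp` Normal predicted OSCC, `fn` OSCC predicted Normal.
#'
#' @param true binary vector of true labels (0/1, logical, or
#'   "Normal"/"OSCC"); 1/"OSCC" is the positive class.
#' @param pred predicted labels, same encoding and length.
#' @return an object of class `stainmil_confusion`: a list with integer
#'   fields `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
#' @export
confusion <- function(true, pred) {
  true <- as_binary_label(true)
  pred <- as_binary_label(pred)
  if (length(true) != length(pred)) {
    stop("`true` and `pred` must have the same length", call. = FALSE)
  }
  cm <- list(
    tp = sum(true == 1L & pred == 1L),
    tn = sum(true == 0L & pred == 0L),
    fp = sum(true == 0L & pred == 1L),
    fn = sum(true == 1L & pred == 0L)
  )
  structure(cm, class = "stainmil_confusion")
}

#' @export
print.stainmil_confusion <- function(x, ...) {
  cat(sprintf(
    "confusion (positive = OSCC): TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
    x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn
  ))
  invisible(x)
}

#' Build a confusion object directly from counts
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @return a `stainmil_confusion` object.
#' @export
confusion_from_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "stainmil_confusion")
}

as_binary_label <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    bad <- !x %in% c("Normal", "OSCC")
    if (any(bad)) stop("labels must be 0/1 or 'Normal'/'OSCC'", call. = FALSE)
    return(as.integer(x == "OSCC"))
  }
  x <- as.integer(x)
  if (any(!x %in% c(0L, 1L))) stop("labels must be binary", call. = FALSE)
  x
}

metric_undefined <- function(what) {
  message(sprintf("%s undefined (zero denominator); returning NA", what))
  NA_real_
}

#' Classification accuracy in percent
#' @param cm a `stainmil_confusion` object.
#' @return accuracy as a percentage in \[0, 100\].
#' @export
accuracy <- function(cm) {
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  if (n == 0) return(metric_undefined("accuracy"))
  100 * (cm$tp + cm$tn) / n
}

#' Precision (positive predictive value) in percent
#' @param cm a `stainmil_confusion` object.
#' @return precision as a percentage, or `NA` when nothing was predicted
#'   positive.
#' @export
precision <- function(cm) {
  d <- cm$tp + cm$fp
  if (d == 0) return(metric_undefined("precision"))
  100 * cm$tp / d
}

#' Recall (sensitivity) in percent
#' @param cm a `stainmil_confusion` object.
#' @return recall as a percentage, or `NA` when there are no positives.
#' @export
recall <- function(cm) {
  d <- cm$tp + cm$fn
  if (d == 0) return(metric_undefined("recall"))
  100 * cm$tp / d
}

#' F1 score from precision and recall (harmonic mean), in percent
#' @param precision,recall percentages in \[0, 100\].
#' @return F1 as a percentage; 0 when both inputs are 0.
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve, in percent
#'
#' Computed as the tie-aware Mann-Whitney rank statistic (midranks), which
#' equals the trapezoidal integral of the empirical ROC curve.
#'
#' @param true binary true labels (1/"OSCC" positive).
#' @param scores numeric scores, larger = more OSCC-like.
#' @return AUC as a percentage, or `NA` for single-class input.
#' @export
auc_score <- function(true, scores) {
  true <- as_binary_label(true)
  if (length(true) != length(scores)) {
    stop("`true` and `scores` must have the same length", call. = FALSE)
  }
  stopifnot_finite(scores, "scores")
  np <- sum(true == 1L)
  nn <- sum(true == 0L)
  if (np == 0 || nn == 0) return(metric_undefined("AUC"))
  r <- rank(scores, ties.method = "average")
  100 * (sum(r[true == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Full metric report from labels and scores
#'
#' @param true binary true labels.
#' @param scores probability of OSCC per sample.
#' @param threshold decision threshold on `scores` (default 0.5).
#' @return a `tibble` with one row: acc, precision, recall, f1, auc (percent)
#'   plus the four confusion counts.
#' @export
metric_report <- function(true, scores, threshold = 0.5) {
  cm <- confusion(as_binary_label(true), as.integer(scores > threshold))
  p <- precision(cm)
  r <- recall(cm)
  tibble::tibble(
    acc = accuracy(cm), precision = p, recall = r, f1 = f1_score(p, r),
    auc = auc_score(true, scores),
    tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn
  )
}
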
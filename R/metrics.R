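#' Confusion counts
#'
#' Either pass the four counts directly or derive them from label
#' vectors (positive class = 1).
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != floor(v))) stopf("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param truth,pred 0/1 label vectors.
#' @export
confusion_from_labels <- function(truth, pred) {
  confusion_counts(tp = sum(truth == 1 & pred == 1),
                   fp = sum(truth == 0 & pred == 1),
                   tn = sum(truth == 0 & pred == 0),
                   fn = sum(truth == 1 & pred == 0))
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2,
              dimnames = list(predicted = c("normal", "abnormal"),
                              actual = c("normal", "abnormal")))
  cat("Confusion matrix:\n")
  print(m)
  invisible(x)
}

# zero-denominator convention: return 0 with a warning
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s has a zero denominator; returning 0", what))
    return(0)
  }
  num / den
}

#' Classification metrics
#'
#' Precision `TP/(TP+FP)`, accuracy `(TP+TN)/total`, recall, and the
#' F1 harmonic mean. Recall has two dialects: `"standard"` is
#' `TP/(TP+FN)`; `"paper"` is the literal printed form `TP/(TN+TP)`,
#' retained for fidelity checks only. Zero denominators yield 0 with
#' a warning.
#'
#' @param c a [confusion_counts()].
#' @param dialect recall dialect, default `"standard"`.
#' @return scalar in `[0, 1]`.
#' @export
precision_metric <- function(c) safe_ratio(c$tp, c$tp + c$fp, "precision")

#' @rdname precision_metric
#' @export
accuracy_metric <- function(c)
  safe_ratio(c$tp + c$tn, c$tp + c$fp + c$tn + c$fn, "accuracy")

#' @rdname precision_metric
#' @export
recall_metric <- function(c, dialect = c("standard", "paper")) {
  dialect <- match.arg(dialect)
  if (dialect == "standard") safe_ratio(c$tp, c$tp + c$fn, "recall")
  else safe_ratio(c$tp, c$tn + c$tp, "recall (paper dialect)")
}

#' @rdname precision_metric
#' @export
f1_metric <- function(c, dialect = c("standard", "paper")) {
  p <- precision_metric(c)
  r <- recall_metric(c, dialect)
  safe_ratio(2 * p * r, p + r, "F1")
}

#' Security ratio and protection level
#'
#' The ratio of compromised to original data, reported both as the raw
#' ratio and as `protection = 1 - ratio` (the conventional "percent
#' secure" reading).
#'
#' @param hacked,original non-negative counts or volumes.
#' @return list with `ratio` and `protection`.
#' @export
security_ratio <- function(hacked, original) {
  r <- safe_ratio(hacked, original, "security ratio")
  list(ratio = r, protection = 1 - r)
}

#' All classification metrics at once
#' @inheritParams precision_metric
#' @return named list: precision, accuracy, recall, f1 (standard
#'   dialect), recall_paper.
#' @export
classification_metrics <- function(c) {
  list(precision = precision_metric(c), accuracy = accuracy_metric(c),
       recall = recall_metric(c, "standard"), f1 = f1_metric(c, "standard"),
       recall_paper = recall_metric(c, "paper"))
}

#' Time a pipeline phase
#'
#' Runs `thunk()` and records elapsed monotonic time (seconds). The
#' durations are hardware-dependent and are quarantined in the run
#' report; they produce no reproducible quantities.
#'
#' @param kind one of "encryption", "key_generation", "decryption" (or
#'   any label).
#' @param thunk a zero-argument function.
#' @return list with `result` and `timing` (kind, start, end,
#'   duration).
#' @export
time_phase <- function(kind, thunk) {
  start <- proc.time()[["elapsed"]]
  result <- thunk()
  end <- proc.time()[["elapsed"]]
  list(result = result,
       timing = list(kind = kind, start = start, end = end,
                     duration = end - start))
}

#' Threshold sweep for an ROC-style curve
#'
#' Qualitative utility: sweeps a probability threshold and returns the
#' true/false positive rates at each point.
#'
#' @param truth 0/1 labels; `prob` abnormal-class probabilities.
#' @param thresholds sweep grid.
#' @return data frame with threshold, tpr, fpr.
#' @export
roc_sweep <- function(truth, prob, thresholds = seq(0, 1, by = 0.01)) {
  do.call(rbind, lapply(thresholds, function(th) {
    pred <- as.integer(prob >= th)
    cc <- confusion_from_labels(truth, pred)
    data.frame(threshold = th,
               tpr = if (cc$tp + cc$fn == 0) 0 else cc$tp / (cc$tp + cc$fn),
               fpr = if (cc$fp + cc$tn == 0) 0 else cc$fp / (cc$fp + cc$tn))
  }))
}
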
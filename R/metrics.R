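#' Detection metrics for imbalanced binary labels
#'
#' Confusion-matrix metrics with the rare deviant class as positive: F1 score
#' (the headline metric under class imbalance), overall accuracy, hit rate
#' (sensitivity on deviants, TP/(TP+FN)) and false alarm rate (FP/(FP+TN)).
#'
#' @param y_true,y_pred equal-length binary vectors (1 = deviant).
#' @return a `detection_metrics` object: list with `f1`, `accuracy`,
#'   `hit_rate`, `false_alarm_rate` and `confusion` (TP, FP, FN, TN). With no
#'   positives in `y_true`, hit rate and F1 are NaN (with a warning).
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stop("labels must be binary")
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  if (tp + fn == 0L) {
    warning("no positive samples in y_true; hit rate and F1 undefined")
    hit <- NaN
    f1 <- NaN
  } else {
    hit <- tp / (tp + fn)
    f1 <- if (2 * tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  far <- if (fp + tn == 0L) NaN else fp / (fp + tn)
  structure(list(f1 = f1, accuracy = (tp + tn) / length(y_true),
                 hit_rate = hit, false_alarm_rate = far,
                 confusion = c(TP = tp, FP = fp, FN = fn, TN = tn)),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("F1 %.3f | accuracy %.3f | hit rate %.3f | false alarm rate %.3f\n",
              x$f1, x$accuracy, x$hit_rate, x$false_alarm_rate))
  cat(sprintf("  confusion: TP %d, FP %d, FN %d, TN %d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["FN"],
              x$confusion["TN"]))
  invisible(x)
}
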
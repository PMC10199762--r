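# label canonicalization: accept epitope/non_epitope strings, factors,
# logicals or 0/1 numerics; epitope (or 1/TRUE) is the positive class
#' @keywords internal
#' @noRd
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("epitope", "non_epitope")))
    stop("labels must be binary (epitope/non_epitope, 0/1 or logical)",
         call. = FALSE)
  as.integer(labels == "epitope")
}

#' Classification metrics for imbalanced binary problems
#'
#' Computes the Matthews correlation coefficient (MCC), ROC AUC, F1 and
#' balanced accuracy plus the confusion matrix at a score threshold.
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as
#' 0 when any factor of the denominator is 0 (the usual convention for
#' degenerate confusion matrices, and the behavior that makes a
#' majority-class predictor score 0 rather than NA on 1:6 data). AUC uses
#' the rank (Mann-Whitney) estimator with average ranks, i.e. tied scores
#' contribute half a concordant pair. F1 is 0 when its denominator is 0.
#'
#' @param labels Binary labels (`epitope`/`non_epitope`, 0/1 or logical;
#'   epitope = positive).
#' @param scores Numeric scores in \[0, 1\] (higher = more epitope-like).
#' @param threshold Decision threshold on the score (default 0.5).
#' @return A list of class `metrics_report`: `mcc`, `roc_auc` (NA when a
#'   class is absent — undefined, not 0.5), `f1`, `balanced_accuracy`,
#'   `tp`, `fp`, `tn`, `fn`, `threshold`, `n`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as_binary_labels(labels)
  stopifnot(length(y) == length(scores), all(scores >= 0), all(scores <= 1))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  auc <- if (npos == 0 || nneg == 0) NA_real_ else {
    r <- rank(scores)  # average ranks: ties count half
    (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  tpr <- if (npos == 0) NA_real_ else tp / npos
  tnr <- if (nneg == 0) NA_real_ else tn / nneg
  bacc <- mean(c(tpr, tnr), na.rm = TRUE)
  structure(list(mcc = mcc, roc_auc = auc, f1 = f1,
                 balanced_accuracy = bacc, tp = tp, fp = fp, tn = tn,
                 fn = fn, threshold = threshold, n = length(y)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  MCC=%.3f  AUC=%s  F1=%.3f  BAcc=%.3f\n",
              x$n, x$mcc,
              if (is.na(x$roc_auc)) "NA" else sprintf("%.3f", x$roc_auc),
              x$f1, x$balanced_accuracy))
  cat(sprintf("  confusion @%.2f: TP=%d FP=%d TN=%d FN=%d\n",
              x$threshold, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
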
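#' ROC curve, AUC and confusion metrics for a score-based classifier
#'
#' Sweeps every distinct score value as a threshold (`>=` semantics, tied
#' scores grouped into one operating point), accumulating the true-positive
#' rate `TPR = TP / positives` and false-positive rate `FPR = FP / negatives`.
#' The area under the curve is computed by the trapezoidal rule and equals the
#' Mann-Whitney probability that a random positive outscores a random negative
#' (ties counted 1/2).
#'
#' @param scores Numeric classifier scores (e.g. composite likelihood ratios).
#' @param labels Logical vector (`TRUE` = positive class), same length.
#' @param cutoff Optional operating threshold at which a confusion matrix,
#'   sensitivity and specificity are reported.
#' @return Object of class `roc_result`: `thresholds` (descending distinct
#'   scores), `tpr`, `fpr` (each starting at the (0,0) point), `auc`, and, if
#'   `cutoff` is given, `confusion` (TP/FP/TN/FN), `sensitivity`,
#'   `specificity`.
#' @export
roc_curve <- function(scores, labels, cutoff = NULL) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  labels <- as.logical(labels)
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0 || N == 0) {
    stop("ROC requires both classes; got ", P, " positives and ", N, " negatives")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  last <- c(which(diff(s) != 0), length(s))   # end index of each tie group
  cumtp <- cumsum(l)
  cumfp <- cumsum(!l)
  tpr <- c(0, cumtp[last] / P)
  fpr <- c(0, cumfp[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- list(thresholds = s[last], tpr = tpr, fpr = fpr, auc = auc)
  if (!is.null(cutoff)) {
    pred <- scores >= cutoff
    tp <- sum(pred & labels)
    fp <- sum(pred & !labels)
    ss <- sensitivity_specificity(tp, fp, P, N)
    out$confusion <- c(TP = tp, FP = fp, TN = N - fp, FN = P - tp)
    out$sensitivity <- ss$sensitivity
    out$specificity <- ss$specificity
    out$cutoff <- cutoff
  }
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC over", length(x$thresholds), "distinct thresholds; AUC =",
      format(x$auc, digits = 4), "\n")
  if (!is.null(x$confusion)) {
    cat("At cutoff", x$cutoff, ":",
        paste(names(x$confusion), x$confusion, sep = "=", collapse = " "),
        sprintf("sensitivity=%.4f specificity=%.4f",
                x$sensitivity, x$specificity), "\n")
  }
  invisible(x)
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / positives`; `specificity = 1 - FP / negatives`.
#'
#' @param tp,fp True-positive and false-positive counts at a threshold.
#' @param positives,negatives Class totals in the test set (must be > 0).
#' @return List with `sensitivity` and `specificity`.
#' @export
sensitivity_specificity <- function(tp, fp, positives, negatives) {
  if (positives <= 0 || negatives <= 0) {
    stop("positives and negatives must both be > 0")
  }
  stopifnot(tp >= 0, fp >= 0, tp <= positives, fp <= negatives)
  list(sensitivity = tp / positives, specificity = 1 - fp / negatives)
}
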
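#' Confusion counts for binary predictions
#'
#' Class 1 (MGMT+) is the positive class. TP/FN count actual positives,
#' TN/FP actual negatives.
#'
#' @param y_true,y_pred equal-length integer vectors with values in
#'   \{0, 1\}.
#' @return a `confusion_counts` list with `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop2("confusion_counts: length mismatch")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    stop2("confusion_counts: labels must be 0 or 1")
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FP = sum(y_true == 0L & y_pred == 1L)),
            class = "confusion_counts")
}

#' The eight performance measures of a confusion matrix
#'
#' Accuracy `A = (TP+TN)/(TP+FP+FN+TN) x 100`, sensitivity
#' `S_n = TP/(TP+FN)`, specificity `S_p = TN/(TN+FP)`, precision
#' `P_r = TP/(TP+FP)`, `NPV = TN/(TN+FN)`, `FPR = FP/(TN+FP)` (the rate
#' measures are reported as percentages), the F1 score
#' `2 P_r R_c / (P_r + R_c)` and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FN)(TP+FP)(TN+FP))` on their
#' natural \[0,1\] / \[-1,1\] scales. Any zero denominator yields a defined
#' 0 and is recorded in `flags`.
#'
#' @param c a [confusion_counts()] (or list with TP/FN/TN/FP).
#' @return a `metrics_report` list.
#' @export
compute_metrics <- function(c) {
  TP <- c$TP; FN <- c$FN; TN <- c$TN; FP <- c$FP
  total <- TP + FN + TN + FP
  if (total == 0) stop2("compute_metrics: all-zero counts")
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); return(0) }
    num / den
  }
  A <- (TP + TN) / total * 100
  S_n <- safe(TP, TP + FN, "S_n") * 100
  S_p <- safe(TN, TN + FP, "S_p") * 100
  P_r <- safe(TP, TP + FP, "P_r") * 100
  NPV <- safe(TN, TN + FN, "NPV") * 100
  FPR <- safe(FP, TN + FP, "FPR") * 100
  F1 <- if (P_r + S_n == 0) { flags <- c(flags, "F1"); 0 } else
    2 * (P_r / 100) * (S_n / 100) / (P_r / 100 + S_n / 100)
  mcc_den <- sqrt(prod(c(TP + FN, TN + FN, TP + FP, TN + FP)))
  MCC <- if (mcc_den == 0) { flags <- c(flags, "MCC"); 0 } else
    (TP * TN - FP * FN) / mcc_den
  structure(list(A = A, S_n = S_n, S_p = S_p, P_r = P_r, NPV = NPV,
                 FPR = FPR, F1 = F1, MCC = MCC, flags = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("A %.2f%%  S_n %.2f%%  S_p %.2f%%  P_r %.2f%%  NPV %.2f%%  F1 %.4f  MCC %.4f\n",
              x$A, x$S_n, x$S_p, x$P_r, x$NPV, x$F1, x$MCC))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC over the TPR/FPR curve, computed as the equivalent rank
#' statistic: the probability that a random positive outscores a random
#' negative, with ties counting one half.
#'
#' @param y_true integer labels in \{0, 1\} (both classes present).
#' @param scores numeric classifier scores (larger = more positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop2("roc_auc: both classes must be present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
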
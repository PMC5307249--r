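#' Classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity TP/(TP+FN), specificity TN/(TN+FP), the
#' geometric mean of the true rates GM = sqrt(sensitivity x specificity),
#' and dominance = sensitivity - specificity. GM and dominance summarize a
#' binary classifier robustly under class imbalance: GM penalizes neglect of
#' either class and dominance exposes which true rate dominates.
#'
#' @param TP,FN,TN,FP nonnegative confusion counts; alternatively pass a
#'   single named list/vector as `TP`.
#' @return Named numeric vector: accuracy, sensitivity, specificity,
#'   geometric_mean, dominance.
#' @examples
#' computeMetrics(TP = 8, FN = 2, TN = 6, FP = 4)
#' @export
computeMetrics <- function(TP, FN = NULL, TN = NULL, FP = NULL) {
  if (is.null(FN)) {
    c0 <- TP
    TP <- c0[["TP"]]; FN <- c0[["FN"]]; TN <- c0[["TN"]]; FP <- c0[["FP"]]
  }
  if (TP + FN == 0 || TN + FP == 0)
    stop("both classes must be represented in the evaluation set")
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  c(accuracy = (TP + TN) / (TP + FN + TN + FP),
    sensitivity = sens, specificity = spec,
    geometric_mean = sqrt(sens * spec),
    dominance = sens - spec)
}

#' Confusion counts for +1 / -1 labels
#'
#' @param truth,pred vectors in {-1, +1}; +1 is the positive
#'   (higher-impairment) class.
#' @return Named vector TP, FN, TN, FP.
#' @export
confusionCounts <- function(truth, pred) {
  c(TP = sum(truth == 1 & pred == 1),
    FN = sum(truth == 1 & pred == -1),
    TN = sum(truth == -1 & pred == -1),
    FP = sum(truth == -1 & pred == 1))
}
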
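#' Fisher's Discriminant Ratio for one feature
#'
#' Computes (mu1 - mu2)^2 / (s1^2 + s2^2), the classical two-class
#' separability score of a single feature, with the population (n) variance
#' convention by default. The ratio is symmetric under class swap and
#' invariant to a common affine rescaling of both classes.
#'
#' @param values1,values2 numeric score vectors for the two classes (each
#'   with at least 2 values).
#' @param variance "population" (divide by n, the classical definition) or
#'   "sample" (divide by n - 1).
#' @return A nonnegative scalar. Both variances zero with equal means gives
#'   0; with unequal means the ratio is undefined and an error is raised.
#' @examples
#' fisherDiscriminantRatio(c(-1, 0, 1), c(1, 2, 3))  # 3
#' @export
fisherDiscriminantRatio <- function(values1, values2,
                                    variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (length(values1) < 2 || length(values2) < 2)
    stop("each class needs at least 2 values")
  pvar <- function(v) {
    s <- sum((v - mean(v))^2)
    s / if (variance == "population") length(v) else (length(v) - 1)
  }
  num <- (mean(values1) - mean(values2))^2
  den <- pvar(values1) + pvar(values2)
  if (den == 0) {
    if (num == 0) return(0)
    stop("both class variances are zero with unequal means: FDR undefined")
  }
  num / den
}

# Vectorized per-column FDR over a standardized matrix and binary labels.
.fdrScores <- function(Z, labels, variance = "population") {
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("FDR reduction requires exactly two classes")
  apply(Z, 2, function(v)
    fisherDiscriminantRatio(v[labels == cls[1]], v[labels == cls[2]],
                            variance = variance))
}

#' Filter features by Fisher's Discriminant Ratio
#'
#' Ranks features by descending FDR and retains the top
#' `ceiling(fraction * n_features)` (the 5% rule retains 7 of 131). Ties are
#' broken deterministically by column (catalog) order.
#'
#' @param Z subjects-by-features matrix of z-scored values, columns in
#'   catalog order.
#' @param labels binary class labels (one per row of `Z`).
#' @param fraction retention fraction in (0, 1]; default 0.05.
#' @param variance variance convention, see [fisherDiscriminantRatio()].
#' @return A \linkS4class{ReductionResult} with strategy `"fdr_filter"`.
#' @examples
#' Z <- cbind(A = c(-1, 0, 1, 5, 6, 7), B = rnorm(6))
#' reduceByFDR(Z, rep(c(0, 1), each = 3), fraction = 0.5)@retained  # "A"
#' @export
reduceByFDR <- function(Z, labels, fraction = 0.05,
                        variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (length(unique(labels)) != 2) stop("labels must be binary")
  scores <- .fdrScores(Z, labels, variance)
  ord <- order(-scores)                       # stable: ties keep catalog order
  ranking <- data.frame(measure = colnames(Z)[ord], score = scores[ord],
                        row.names = NULL)
  k <- ceiling(fraction * ncol(Z))
  new("ReductionResult", strategy = "fdr_filter", ranking = ranking,
      retained = ranking$measure[seq_len(k)],
      provenance = list(fraction = fraction, variance = variance,
                        n_features = ncol(Z), n_subjects = nrow(Z)))
}

#' Rank expert-retained measures by single-feature classification accuracy
#'
#' Each candidate measure is used alone as classifier input under the same
#' class-balanced 10-fold machinery as the main run (no subset search):
#' per iteration the two classes are balanced by undersampling and split
#' into stratified folds; per round a z-score model and an SVM are fitted on
#' the training folds and the held-out fold is scored. The per-measure
#' accuracy is averaged across all rounds and iterations, measures are
#' ranked in descending order, and the top `top` (default 10) are retained,
#' ties broken by catalog order.
#'
#' @param cohort an \linkS4class{NPCohort}.
#' @param task comparison label: "0.5v0", "1v0" or "1v0.5" (positive =
#'   higher CDR).
#' @param measures candidate measure names; defaults to the expert-retained
#'   measures of the cohort's catalog.
#' @param kernel a \linkS4class{KernelConfig}; default linear.
#' @param rounds folds of the balanced cross-validation (default 10).
#' @param iterations balanced resampling repetitions (default 100).
#' @param top retention cut-off (default 10); with fewer candidates than
#'   `top` all are retained with a warning.
#' @param seed master seed for balancing and fold assignment.
#' @return A \linkS4class{ReductionResult} with strategy
#'   `"expert_accuracy"`; the ranking's `score` column is mean accuracy.
#' @export
rankBySingleFeatureAccuracy <- function(cohort, task, measures = NULL,
                                        kernel = kernelConfig("linear"),
                                        rounds = 10L, iterations = 100L,
                                        top = 10L, seed = 1L) {
  tk <- .parseTask(task)
  if (is.null(measures)) {
    rd <- cohortCatalog(cohort)
    measures <- rd$name[rd$expert_retained]
  }
  X <- scoreMatrix(cohort)
  missing <- setdiff(measures, colnames(X))
  if (length(missing))
    stop("measure(s) absent from cohort: ", paste(missing, collapse = ", "))
  lab <- cdrLabels(cohort)
  keep <- lab %in% c(tk$pos, tk$neg)
  X <- X[keep, measures, drop = FALSE]
  y <- ifelse(lab[keep] == tk$pos, 1, -1)

  set.seed(seed)
  iterSeeds <- sample.int(.Machine$integer.max, iterations)
  acc <- matrix(NA_real_, length(measures), iterations * rounds,
                dimnames = list(measures, NULL))
  col <- 0L
  for (it in seq_len(iterations)) {
    set.seed(iterSeeds[it])
    bal <- balanceClasses(y)
    folds <- .stratifiedFolds(y[bal], rounds)
    Xb <- X[bal, , drop = FALSE]; yb <- y[bal]
    for (r in seq_len(rounds)) {
      col <- col + 1L
      tr <- folds != r; te <- !tr
      for (m in measures) {
        Xm <- Xb[, m, drop = FALSE]
        if (sd(Xm[tr, 1]) == 0) next        # constant in training: skip fold
        zs <- fitZScore(Xm, subset = which(tr))
        fit <- tryCatch(trainSVM(applyZScore(zs, Xm[tr, , drop = FALSE]),
                                 yb[tr], kernel),
                        error = function(e) NULL)
        if (is.null(fit)) next
        pred <- predictSVM(fit, applyZScore(zs, Xm[te, , drop = FALSE]))
        acc[m, col] <- mean(pred == yb[te])
      }
    }
  }
  meanAcc <- rowMeans(acc, na.rm = TRUE)
  ord <- order(-meanAcc)
  ranking <- data.frame(measure = measures[ord], score = unname(meanAcc[ord]),
                        row.names = NULL)
  k <- min(top, length(measures))
  if (length(measures) < top)
    warning(sprintf("only %d candidate measures; retaining all",
                    length(measures)))
  new("ReductionResult", strategy = "expert_accuracy", ranking = ranking,
      retained = ranking$measure[seq_len(k)],
      provenance = list(task = task, kernel = kernel@kind, rounds = rounds,
                        iterations = iterations, top = top, seed = seed))
}

#' Write a reduction result
#'
#' `writeReductionTSV` emits the two-column (measure, score) ranking;
#' `writeReductionJSON` the full object including the retained set and
#' provenance.
#'
#' @param result a \linkS4class{ReductionResult}.
#' @param path output file path.
#' @export
writeReductionTSV <- function(result, path) {
  utils::write.table(result@ranking, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeReductionTSV
#' @export
writeReductionJSON <- function(result, path) {
  jsonlite::write_json(list(strategy = result@strategy,
                            ranking = result@ranking,
                            retained = result@retained,
                            provenance = result@provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

setMethod("show", "ReductionResult", function(object) {
  cat(sprintf("ReductionResult (%s): %d ranked, %d retained\n",
              object@strategy, nrow(object@ranking),
              length(object@retained)))
  cat("  retained:", paste(object@retained, collapse = ", "), "\n")
})
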
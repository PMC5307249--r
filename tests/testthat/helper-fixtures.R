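# Shared fixtures: small catalogs and cohorts built in code at test time.

# Sub-catalog restricted to the given measure names (catalog order kept).
tinyCatalog <- function(keep) {
  selectMeasures(defaultCatalog(), name %in% keep)
}

# Wide-range, non-binary measures from distinct instruments: convenient for
# small cohorts because no fold can make them constant in practice.
WIDE_MEASURES <- c("LDELTOTAL", "MMSCORE", "CLOCKSCOR", "AVTOTB", "DSPANFOR",
                   "CATVEGESC", "TRAASCOR", "BNTTOTAL", "Q14", "GDTOTAL")

# Cohort with one strongly planted measure (LDELTOTAL) among noise measures
# drawn from other instruments, so within-instrument correlation never
# couples the noise to the signal.
plantedCohort <- function(nPerGroup = 40, shift1 = 2.0, shift05 = 1.0,
                          seed = 5, measures = WIDE_MEASURES) {
  cfg <- cohortConfig(
    groupSizes = c("0" = nPerGroup, "0.5" = 10, "1" = nPerGroup),
    planted = list(LDELTOTAL = c(0, shift05, shift1)),
    seed = seed)
  generateCohort(cfg, tinyCatalog(measures))
}

nullCohort <- function(nPerGroup = 40, seed = 5, measures = WIDE_MEASURES) {
  cfg <- cohortConfig(
    groupSizes = c("0" = nPerGroup, "0.5" = 10, "1" = nPerGroup),
    planted = list(), seed = seed)
  generateCohort(cfg, tinyCatalog(measures))
}

# Minimal hand-built NestedCVResult carrying only what frequency/reporting
# code consumes.
fakeCVResult <- function(subsets, featureOrder,
                         task = "1v0", kernelKind = "linear",
                         records = NULL) {
  n <- length(subsets)
  if (is.null(records)) {
    records <- data.frame(round = seq_len(n), iteration = 1L,
                          inner_accuracy = 1, accuracy = 1, sensitivity = 1,
                          specificity = 1, geometric_mean = 1, dominance = 0)
  }
  new("NestedCVResult", task = task, strategy = "fdr",
      kernel = kernelConfig(kernelKind), rounds = as.integer(n),
      iterations = 1L, records = records, subsets = subsets,
      reduced = rep(list(featureOrder), n),
      folds = list(list(subjects = 1:2, fold = 1:2, seed = 1)),
      featureOrder = featureOrder,
      failures = data.frame(round = integer(), iteration = integer(),
                            stage = character(), message = character()),
      seed = 1L)
}

# Independent pooled inner-CV accuracy, written against the stored fold
# plan only (brute-force oracle for subset-selection checks).
bruteInnerAccuracy <- function(Z, y, fold, outerRound, cols, kernel) {
  trainFolds <- setdiff(sort(unique(fold)), outerRound)
  hits <- 0; total <- 0
  for (f in trainFolds) {
    tr <- which(fold %in% setdiff(trainFolds, f))
    va <- which(fold == f)
    fit <- trainSVM(Z[tr, cols, drop = FALSE], y[tr], kernel)
    hits <- hits + sum(predictSVM(fit, Z[va, cols, drop = FALSE]) == y[va])
    total <- total + length(va)
  }
  hits / total
}
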
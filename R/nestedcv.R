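# Comparison tasks: positive class = higher CDR level, so sensitivity is
# detection of (greater) impairment.
.TASKS <- list("0.5v0" = list(pos = 0.5, neg = 0),
               "1v0"   = list(pos = 1,   neg = 0),
               "1v0.5" = list(pos = 1,   neg = 0.5))

.parseTask <- function(task) {
  if (!task %in% names(.TASKS))
    stop("task must be one of: ", paste(names(.TASKS), collapse = ", "))
  .TASKS[[task]]
}

#' Balance two classes by undersampling
#'
#' Randomly undersamples the majority class without replacement to the
#' minority size, using the current RNG state (callers seed per iteration
#' so every iteration draws a fresh balanced subsample).
#'
#' @param labels vector of two class labels.
#' @return Integer indices of the balanced subject subset (sorted).
#' @examples
#' set.seed(1)
#' table(rep(c("a", "b"), c(30, 50))[balanceClasses(rep(c("a", "b"), c(30, 50)))])
#' @export
balanceClasses <- function(labels) {
  cls <- unique(labels)
  if (length(cls) != 2) stop("expected exactly two classes")
  idx <- split(seq_along(labels), labels)
  sizes <- lengths(idx)
  if (any(sizes == 0)) stop("a class has no members")
  m <- min(sizes)
  sort(unlist(lapply(idx, function(i)
    if (length(i) == m) i else sample(i, m)), use.names = FALSE))
}

# Stratified fold assignment: within each class, subjects are dealt evenly
# across the k folds (per-fold class counts differ by at most 1). The two
# classes place their remainder subjects at opposite ends of one random fold
# permutation, so total fold sizes also differ by at most 1.
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  cls <- unique(labels)
  p <- sample(k)
  for (j in seq_along(cls)) {
    i <- which(labels == cls[j])
    base <- rep(seq_len(k), length(i) %/% k)
    r <- length(i) %% k
    extra <- if (r == 0) integer() else
      if (j %% 2 == 1) p[seq_len(r)] else p[k + 1 - seq_len(r)]
    fold[i] <- sample(c(base, extra))
  }
  fold
}

#' Enumerate all nonempty feature subsets
#'
#' Returns every nonempty subset of the given features, ordered by
#' cardinality and then lexicographically by feature position. This order
#' makes the inner-loop maximum deterministic: among equally accurate
#' subsets the smallest, earliest-in-catalog one is chosen.
#'
#' @param features character vector of feature names (at most 20, guarding
#'   against combinatorial explosion).
#' @return List of 2^k - 1 character vectors.
#' @examples
#' length(enumerateSubsets(letters[1:3]))  # 7
#' @export
enumerateSubsets <- function(features) {
  k <- length(features)
  if (k < 1) stop("need at least one feature")
  if (k > 20)
    stop("refusing to enumerate 2^", k, " subsets; lower the reduction ",
         "cut-off so at most 20 features remain")
  out <- vector("list", 2^k - 1)
  pos <- 0L
  for (size in seq_len(k)) {
    combos <- combn(k, size)
    for (j in seq_len(ncol(combos))) {
      pos <- pos + 1L
      out[[pos]] <- features[combos[, j]]
    }
  }
  out
}

# Pooled inner-CV accuracy of one candidate subset: each training fold is
# held out in turn, the SVM is trained on the remaining folds, and all
# inner-validation predictions are pooled into a single accuracy.
.innerAccuracy <- function(Z, y, fold, trainFolds, cols, kernel) {
  good <- 0L; total <- 0L
  for (f in trainFolds) {
    tr <- fold != f & fold %in% trainFolds
    va <- fold == f
    fit <- tryCatch(trainSVM(Z[tr, cols, drop = FALSE], y[tr], kernel),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pred <- predictSVM(fit, Z[va, cols, drop = FALSE])
    good <- good + sum(pred == y[va]); total <- total + sum(va)
  }
  good / total
}

# Per-round single-feature accuracy ranking (strategy "expert" inside the
# nested CV): candidates are scored by inner-CV accuracy on the training
# folds only, then the top `top` are retained.
.rankFeaturesInner <- function(Z, y, fold, trainFolds, features, kernel, top) {
  acc <- vapply(features, function(m)
    .innerAccuracy(Z, y, fold, trainFolds, m, kernel), 0)
  ord <- order(-acc)
  features[ord][seq_len(min(top, length(features)))]
}

#' Nested cross-validation with exhaustive feature-subset optimization
#'
#' The evaluation engine: per iteration the two task classes are balanced by
#' undersampling and split into `rounds` stratified outer folds. Per round,
#' z-score normalization and the feature reduction are fitted on the
#' training folds only (leakage-free default); every nonempty subset of the
#' reduced features is scored by inner cross-validation over the training
#' folds (each held out in turn); the subset with maximum inner accuracy is
#' selected (ties: smallest subset, then catalog order), refitted on all
#' training folds, and evaluated on the held-out outer fold. The whole
#' procedure is repeated `iterations` times, yielding `rounds x iterations`
#' optimal subsets and outer metric sets.
#'
#' @param cohort an \linkS4class{NPCohort}.
#' @param task "0.5v0", "1v0" or "1v0.5" (positive class = higher CDR).
#' @param strategy per-round reduction: "fdr" (Fisher's Discriminant Ratio
#'   filter, see [reduceByFDR()]), "expert" (restrict to expert-retained
#'   measures, then per-round single-feature-accuracy top-`top` ranking), or
#'   "none" (use all cohort measures, subject to the 20-feature guard).
#' @param kernel a \linkS4class{KernelConfig}.
#' @param rounds outer folds per iteration (default 10).
#' @param iterations balanced resampling repetitions (default 100).
#' @param fdrFraction retention fraction of the FDR filter (default 0.05).
#' @param top retention count of the expert strategy (default 10).
#' @param fdrVariance variance convention of the FDR filter.
#' @param reductionScope "fold" refits the reduction per round (default);
#'   "global" fits it once on the full task sample, reproducing the literal
#'   fixed-feature-set reading.
#' @param zscoreScope "fold" (default) or "global", likewise.
#' @param seed master seed; per-iteration seeds are drawn from it and
#'   recorded, so any iteration can be replayed in isolation.
#' @param verbose print per-iteration progress.
#' @return A \linkS4class{NestedCVResult}.
#' @seealso [cvSummary()], [innerOuterByRound()],
#'   [bestPredictorFrequencies()]
#' @export
runNestedCV <- function(cohort, task,
                        strategy = c("fdr", "expert", "none"),
                        kernel = kernelConfig("linear"),
                        rounds = 10L, iterations = 100L,
                        fdrFraction = 0.05, top = 10L,
                        fdrVariance = c("population", "sample"),
                        reductionScope = c("fold", "global"),
                        zscoreScope = c("fold", "global"),
                        seed = 1L, verbose = FALSE) {
  strategy <- match.arg(strategy)
  fdrVariance <- match.arg(fdrVariance)
  reductionScope <- match.arg(reductionScope)
  zscoreScope <- match.arg(zscoreScope)
  tk <- .parseTask(task)
  rounds <- as.integer(rounds); iterations <- as.integer(iterations)

  X <- scoreMatrix(cohort)
  lab <- cdrLabels(cohort)
  keep <- lab %in% c(tk$pos, tk$neg)
  if (!any(lab[keep] == tk$pos) || !any(lab[keep] == tk$neg))
    stop("cohort lacks one of the task's CDR levels")
  X <- X[keep, , drop = FALSE]
  y <- ifelse(lab[keep] == tk$pos, 1, -1)
  if (strategy == "expert") {
    rd <- cohortCatalog(cohort)
    exp_meas <- intersect(rd$name[rd$expert_retained], colnames(X))
    if (!length(exp_meas)) stop("no expert-retained measures in cohort")
    X <- X[, exp_meas, drop = FALSE]
  }
  featureOrder <- colnames(X)

  # Global (whole-sample) variants of the literal reading, fitted once.
  globalZ <- NULL; globalRetained <- NULL
  if (zscoreScope == "global" || reductionScope == "global") {
    usable <- featureOrder[apply(X, 2, sd) > 0]
    gz <- fitZScore(X[, usable, drop = FALSE])
    if (zscoreScope == "global") globalZ <- gz
    if (reductionScope == "global") {
      Zg <- applyZScore(gz, X)
      globalRetained <- switch(strategy,
        fdr = reduceByFDR(Zg, y, fdrFraction, fdrVariance)@retained,
        expert = stop("global reduction scope is not defined for the ",
                      "expert strategy; use reductionScope = 'fold'"),
        none = usable)
    }
  }

  set.seed(seed)
  iterSeeds <- sample.int(.Machine$integer.max, iterations)

  n_rec <- rounds * iterations
  records <- data.frame(round = integer(n_rec), iteration = integer(n_rec),
                        inner_accuracy = NA_real_, accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        geometric_mean = NA_real_, dominance = NA_real_)
  subsets <- vector("list", n_rec)
  reduced <- vector("list", n_rec)
  folds <- vector("list", iterations)
  failures <- data.frame(round = integer(), iteration = integer(),
                         stage = character(), message = character())
  rec <- 0L
  for (it in seq_len(iterations)) {
    set.seed(iterSeeds[it])
    bal <- balanceClasses(y)
    yb <- y[bal]
    fold <- .stratifiedFolds(yb, rounds)
    folds[[it]] <- list(subjects = bal, fold = fold, seed = iterSeeds[it])
    Xb <- X[bal, , drop = FALSE]
    for (r in seq_len(rounds)) {
      rec <- rec + 1L
      records$round[rec] <- r; records$iteration[rec] <- it
      tr <- fold != r; te <- !tr
      trainFolds <- setdiff(seq_len(rounds), r)

      usable <- featureOrder[apply(Xb[tr, , drop = FALSE], 2, sd) > 0]
      zs <- if (is.null(globalZ))
        fitZScore(Xb[, usable, drop = FALSE], subset = which(tr)) else globalZ
      Z <- applyZScore(zs, Xb)

      retained <- if (!is.null(globalRetained))
        intersect(globalRetained, colnames(Z))
      else switch(strategy,
        fdr = reduceByFDR(Z[tr, , drop = FALSE], yb[tr], fdrFraction,
                          fdrVariance)@retained,
        expert = .rankFeaturesInner(Z, yb, fold, trainFolds, colnames(Z),
                                    kernel, top),
        none = colnames(Z))
      reduced[[rec]] <- retained

      cand <- enumerateSubsets(retained)
      innerAcc <- vapply(cand, function(s)
        .innerAccuracy(Z, yb, fold, trainFolds, s, kernel), 0)
      if (all(is.na(innerAcc))) {
        failures <- rbind(failures, data.frame(
          round = r, iteration = it, stage = "inner",
          message = "solver failed for every candidate subset"))
        subsets[[rec]] <- character()
        next
      }
      best <- which.max(innerAcc)       # first max: smallest, catalog-first
      subsets[[rec]] <- cand[[best]]
      records$inner_accuracy[rec] <- innerAcc[best]

      fit <- tryCatch(
        trainSVM(Z[tr, cand[[best]], drop = FALSE], yb[tr], kernel),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures <- rbind(failures, data.frame(
          round = r, iteration = it, stage = "outer",
          message = conditionMessage(fit)))
        next
      }
      pred <- predictSVM(fit, Z[te, cand[[best]], drop = FALSE])
      m <- computeMetrics(confusionCounts(yb[te], pred))
      records[rec, names(m)] <- as.list(m)
    }
    if (verbose)
      message(sprintf("iteration %d/%d done", it, iterations))
  }
  new("NestedCVResult", task = task, strategy = strategy, kernel = kernel,
      rounds = rounds, iterations = iterations, records = records,
      subsets = subsets, reduced = reduced, folds = folds,
      featureOrder = featureOrder, failures = failures,
      seed = as.integer(seed))
}

#' Aggregate nested-CV metrics
#'
#' Mean and standard deviation of each outer-loop metric (and the selected
#' subsets' inner accuracy) across all rounds x iterations, excluding
#' solver-failed rounds (logged in the result's `failures` slot).
#'
#' @param result a \linkS4class{NestedCVResult}.
#' @return data.frame with columns metric, mean, sd.
#' @export
cvSummary <- function(result) {
  cols <- c("inner_accuracy", "accuracy", "sensitivity", "specificity",
            "geometric_mean", "dominance")
  data.frame(metric = cols,
             mean = vapply(cols, function(cn)
               mean(result@records[[cn]], na.rm = TRUE), 0),
             sd = vapply(cols, function(cn)
               sd(result@records[[cn]], na.rm = TRUE), 0),
             row.names = NULL)
}

#' Per-round inner and outer accuracy
#'
#' Averages the inner-loop accuracy of the selected subsets and the
#' outer-loop accuracy across iterations, per round -- the per-round view of
#' selection optimism (inner accuracy typically exceeds outer).
#'
#' @param result a \linkS4class{NestedCVResult}.
#' @return data.frame with one row per round plus a total row: mean and sd
#'   of inner and outer accuracy across iterations.
#' @export
innerOuterByRound <- function(result) {
  rc <- result@records
  per <- do.call(rbind, lapply(seq_len(result@rounds), function(r) {
    s <- rc[rc$round == r, ]
    data.frame(round = as.character(r),
               inner_mean = mean(s$inner_accuracy, na.rm = TRUE),
               inner_sd = sd(s$inner_accuracy, na.rm = TRUE),
               outer_mean = mean(s$accuracy, na.rm = TRUE),
               outer_sd = sd(s$accuracy, na.rm = TRUE))
  }))
  rbind(per, data.frame(round = "total",
                        inner_mean = mean(rc$inner_accuracy, na.rm = TRUE),
                        inner_sd = sd(rc$inner_accuracy, na.rm = TRUE),
                        outer_mean = mean(rc$accuracy, na.rm = TRUE),
                        outer_sd = sd(rc$accuracy, na.rm = TRUE)))
}

#' Best-predictor frequencies
#'
#' For each feature, the percentage of optimal subsets (one per round x
#' iteration) containing it -- the measure-importance statistic of the
#' pipeline. Frequencies need not sum to 100% because subsets overlap.
#'
#' @param result a \linkS4class{NestedCVResult}.
#' @param top how many top features to return (default 10; `Inf` for all).
#' @return data.frame with columns measure, count, percent, in descending
#'   percent order, ties broken by catalog order.
#' @export
bestPredictorFrequencies <- function(result, top = 10) {
  subs <- result@subsets
  counts <- setNames(numeric(length(result@featureOrder)),
                     result@featureOrder)
  tab <- table(unlist(subs))
  counts[names(tab)] <- as.numeric(tab)
  ord <- order(-counts)
  out <- data.frame(measure = names(counts)[ord],
                    count = unname(counts[ord]),
                    percent = 100 * unname(counts[ord]) / length(subs),
                    row.names = NULL)
  utils::head(out, n = min(top, nrow(out)))
}

setMethod("show", "NestedCVResult", function(object) {
  cat(sprintf(
    "NestedCVResult: task %s, %s reduction, %s kernel, %d rounds x %d iterations\n",
    object@task, object@strategy, object@kernel@kind, object@rounds,
    object@iterations))
  s <- cvSummary(object)
  acc <- s[s$metric == "accuracy", ]
  cat(sprintf("  outer accuracy %.2f +/- %.2f; %d solver failure(s)\n",
              acc$mean, acc$sd, nrow(object@failures)))
})
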
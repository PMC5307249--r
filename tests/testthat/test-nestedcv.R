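test_that("class balancing undersamples the majority to the minority size", {
  set.seed(50)
  lab <- rep(c("a", "b"), c(30, 50))
  idx <- balanceClasses(lab)
  expect_equal(as.vector(table(lab[idx])), c(30, 30))
  lab2 <- rep(c(0, 1), c(126, 55))
  idx2 <- balanceClasses(lab2)
  expect_equal(as.vector(table(lab2[idx2])), c(55, 55))
  even <- rep(c(0, 1), each = 12)
  expect_equal(balanceClasses(even), seq_along(even))
  expect_error(balanceClasses(rep("a", 5)), "two classes")
})

test_that("subset enumeration is complete and deterministically ordered", {
  expect_length(enumerateSubsets("x"), 1)
  s3 <- enumerateSubsets(c("a", "b", "c"))
  expect_length(s3, 7)
  expect_equal(s3[[1]], "a")
  expect_equal(s3[[4]], c("a", "b"))          # cardinality then lexicographic
  expect_equal(s3[[7]], c("a", "b", "c"))
  expect_length(enumerateSubsets(paste0("f", 1:10)), 1023)
  expect_error(enumerateSubsets(paste0("f", 1:21)), "20 features")
  expect_error(enumerateSubsets(character()), "at least one")
})

test_that("fold plans partition the balanced sample with near-equal strata", {
  co <- plantedCohort(nPerGroup = 43, seed = 51)
  res <- runNestedCV(co, "1v0", strategy = "fdr", fdrFraction = 0.2,
                     rounds = 10, iterations = 3, seed = 52)
  y <- ifelse(cdrLabels(co)[cdrLabels(co) %in% c(0, 1)] == 1, 1, -1)
  for (fp in res@folds) {
    expect_equal(as.vector(table(y[fp$subjects])), c(43, 43))
    expect_length(fp$fold, 86)
    sizes <- table(fp$fold)
    expect_lte(diff(range(sizes)), 1)
    for (r in 1:10) {
      cls <- table(y[fp$subjects][fp$fold == r])
      expect_lte(abs(diff(as.vector(cls))), 1)
    }
  }
})

test_that("a full grid records exactly rounds x iterations optimal subsets", {
  co <- plantedCohort(nPerGroup = 20, seed = 53,
                      measures = WIDE_MEASURES[1:4])
  res <- runNestedCV(co, "1v0", strategy = "fdr", fdrFraction = 0.5,
                     rounds = 5, iterations = 4, seed = 54)
  expect_length(res@subsets, 20)
  expect_equal(nrow(res@records), 20)
  expect_true(all(lengths(res@subsets) >= 1))
  for (i in seq_along(res@subsets))
    expect_true(all(res@subsets[[i]] %in% res@reduced[[i]]))
})

test_that("the selected subset attains the brute-force inner maximum", {
  co <- plantedCohort(nPerGroup = 25, shift1 = 1.2, seed = 55,
                      measures = WIDE_MEASURES[1:5])
  kern <- kernelConfig("linear")
  res <- runNestedCV(co, "1v0", strategy = "fdr", fdrFraction = 0.8,
                     rounds = 10, iterations = 1, seed = 56)
  lab <- cdrLabels(co)[cdrLabels(co) %in% c(0, 1)]
  X <- scoreMatrix(co)[cdrLabels(co) %in% c(0, 1), ]
  y <- ifelse(lab == 1, 1, -1)
  fp <- res@folds[[1]]
  Xb <- X[fp$subjects, ]; yb <- y[fp$subjects]
  for (r in c(1, 4, 8)) {
    rec <- which(res@records$round == r & res@records$iteration == 1)
    tr <- fp$fold != r
    zs <- fitZScore(Xb, subset = which(tr))
    Z <- applyZScore(zs, Xb)
    cand <- enumerateSubsets(res@reduced[[rec]])
    acc <- vapply(cand, function(s)
      bruteInnerAccuracy(Z, yb, fp$fold, r, s, kern), 0)
    expect_equal(res@records$inner_accuracy[rec], max(acc))
    best <- which.max(acc)   # first max = tie rule
    expect_equal(res@subsets[[rec]], cand[[best]])
  }
})

test_that("identical master seeds reproduce the whole result", {
  co <- plantedCohort(nPerGroup = 15, seed = 57,
                      measures = WIDE_MEASURES[1:4])
  r1 <- runNestedCV(co, "1v0", strategy = "fdr", fdrFraction = 0.5,
                    rounds = 5, iterations = 2, seed = 58)
  r2 <- runNestedCV(co, "1v0", strategy = "fdr", fdrFraction = 0.5,
                    rounds = 5, iterations = 2, seed = 58)
  expect_identical(r1@records, r2@records)
  expect_identical(r1@subsets, r2@subsets)
  expect_identical(r1@folds, r2@folds)
  r3 <- runNestedCV(co, "1v0", strategy = "fdr", fdrFraction = 0.5,
                    rounds = 5, iterations = 2, seed = 59)
  expect_false(identical(r1@subsets, r3@subsets) &&
               identical(r1@records, r2@records) &&
               identical(r1@folds, r3@folds))
})

test_that("inner accuracy exceeds outer accuracy on average", {
  co <- plantedCohort(nPerGroup = 30, shift1 = 1.0, seed = 60,
                      measures = WIDE_MEASURES[1:6])
  res <- runNestedCV(co, "1v0", strategy = "fdr", fdrFraction = 0.5,
                     rounds = 10, iterations = 5, seed = 61)
  s <- cvSummary(res)
  expect_gt(s$mean[s$metric == "inner_accuracy"],
            s$mean[s$metric == "accuracy"])
})

test_that("the expert strategy restricts candidates to retained measures", {
  co <- generateCohort(cohortConfig(
    groupSizes = c("0" = 15, "0.5" = 10, "1" = 15),
    planted = list(LDELTOTAL = c(0, 1, 2)), seed = 62),
    tinyCatalog(c("LDELTOTAL", "MMSCORE", "ANARTERR", "BNTSPONT",
                  "FAQTOTAL")))
  res <- runNestedCV(co, "1v0", strategy = "expert", top = 2,
                     rounds = 5, iterations = 1, seed = 63)
  expect_true(all(unlist(res@subsets) %in%
                  c("LDELTOTAL", "MMSCORE", "FAQTOTAL")))
  expect_true(all(lengths(res@reduced) == 2))
})

test_that("global scopes reproduce the fixed-feature-set reading", {
  co <- plantedCohort(nPerGroup = 20, seed = 64,
                      measures = WIDE_MEASURES[1:5])
  res <- runNestedCV(co, "1v0", strategy = "fdr", fdrFraction = 0.4,
                     rounds = 5, iterations = 2, seed = 65,
                     reductionScope = "global", zscoreScope = "global")
  expect_length(unique(res@reduced), 1)   # one fixed reduced set
  expect_length(res@reduced[[1]], 2)
  expect_error(
    runNestedCV(co, "1v0", strategy = "expert", reductionScope = "global",
                rounds = 5, iterations = 1, seed = 66),
    "not defined")
})

test_that("best-predictor frequencies match a hand-counted example", {
  subsets <- list(c("A", "B"), "A", c("B", "C"), c("A", "C"))
  res <- fakeCVResult(subsets, featureOrder = c("A", "B", "C"))
  freq <- bestPredictorFrequencies(res, top = Inf)
  expect_equal(freq$measure, c("A", "B", "C"))
  expect_equal(freq$percent, c(75, 50, 50))
  expect_gt(sum(freq$percent), 100)       # overlap: no sum constraint
  one <- bestPredictorFrequencies(fakeCVResult(list("A", "A"), c("A", "B")),
                                  top = 1)
  expect_equal(one$percent, 100)
})

test_that("frequency ties are broken by catalog order", {
  subsets <- list(c("z_late", "a_early"), c("a_early", "z_late"))
  res <- fakeCVResult(subsets, featureOrder = c("z_late", "a_early"))
  freq <- bestPredictorFrequencies(res, top = Inf)
  expect_equal(freq$measure, c("z_late", "a_early"))
})

test_that("missing task levels and bad task labels are rejected", {
  co <- plantedCohort(nPerGroup = 15, seed = 67,
                      measures = WIDE_MEASURES[1:3])
  expect_error(runNestedCV(co, "2v0", rounds = 5, iterations = 1),
               "task must be one of")
  co01 <- co[, cdrLabels(co) %in% c(0, 1)]
  expect_error(runNestedCV(new("NPCohort", co01), "1v0.5",
                           rounds = 5, iterations = 1),
               "lacks one of the task")
})
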
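test_that("Fisher's discriminant ratio matches a hand oracle", {
  # means 0 and 2; population variances 2/3 each; 4 / (4/3) = 3
  expect_equal(fisherDiscriminantRatio(c(-1, 0, 1), c(1, 2, 3)), 3.0)
  expect_equal(fisherDiscriminantRatio(c(1, 2, 3), c(-1, 0, 1)), 3.0)
  expect_equal(fisherDiscriminantRatio(c(1, 2, 3), c(3, 2, 1)), 0)
  # sample convention: variances 1 each; 4 / 2 = 2
  expect_equal(fisherDiscriminantRatio(c(-1, 0, 1), c(1, 2, 3),
                                       variance = "sample"), 2.0)
})

test_that("degenerate FDR inputs follow the stated contract", {
  expect_equal(fisherDiscriminantRatio(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_error(fisherDiscriminantRatio(c(2, 2), c(3, 3)), "undefined")
  expect_error(fisherDiscriminantRatio(1, c(1, 2)), "at least 2")
})

test_that("FDR is invariant under a common affine transform", {
  set.seed(20)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20, 1)
    s <- runif(1, 0.1, 10); t <- runif(1, -5, 5)
    expect_lt(abs(fisherDiscriminantRatio(a, b) -
                  fisherDiscriminantRatio(a * s + t, b * s + t)), 1e-9)
  }
})

test_that("FDR retention counts follow the ceiling rule", {
  set.seed(21)
  labels <- rep(c(0, 1), each = 20)
  Z131 <- matrix(rnorm(40 * 131), 40, dimnames = list(NULL, paste0("f", 1:131)))
  expect_length(reduceByFDR(Z131, labels, 0.05)@retained, 7)
  expect_length(reduceByFDR(Z131, labels, 1.0)@retained, 131)
  Z50 <- Z131[, 1:50]
  expect_length(reduceByFDR(Z50, labels, 0.05)@retained, 3)
  expect_error(reduceByFDR(Z131, rep(1, 40), 0.05), "binary")
  expect_error(reduceByFDR(Z131, labels, 0), "fraction")
})

test_that("FDR ranking agrees with a brute-force sort oracle", {
  set.seed(22)
  for (rep in 1:5) {
    labels <- rep(c(0, 1), each = 15)
    Z <- matrix(rnorm(30 * 20), 30, dimnames = list(NULL, paste0("f", 1:20)))
    res <- reduceByFDR(Z, labels, fraction = 0.25)
    oracle <- vapply(colnames(Z), function(cn) {
      a <- Z[labels == 0, cn]; b <- Z[labels == 1, cn]
      (mean(a) - mean(b))^2 /
        (mean((a - mean(a))^2) + mean((b - mean(b))^2))
    }, 0)
    expect_equal(res@ranking$measure, names(sort(-oracle)))
    expect_equal(res@ranking$score, unname(sort(oracle, decreasing = TRUE)),
                 tolerance = 1e-12)
    expect_equal(res@retained, names(sort(-oracle))[1:5])
  }
})

test_that("ties in FDR are broken by catalog (column) order", {
  labels <- rep(c(0, 1), each = 4)
  v <- c(0, 0, 1, 1, 2, 2, 3, 3)
  Z <- cbind(b_first = v, a_second = v)   # identical scores
  res <- reduceByFDR(Z, labels, fraction = 0.5)
  expect_equal(res@retained, "b_first")
  expect_equal(res@ranking$measure, c("b_first", "a_second"))
})

test_that("increasing a planted shift never lowers that feature's FDR rank", {
  ranks <- vapply(c(0.25, 0.5, 1, 1.5, 2), function(shift) {
    set.seed(23)
    labels <- rep(c(0, 1), each = 60)
    Z <- matrix(rnorm(120 * 10), 120, dimnames = list(NULL, paste0("f", 1:10)))
    Z[labels == 1, "f1"] <- Z[labels == 1, "f1"] + shift
    match("f1", reduceByFDR(Z, labels, 1.0)@ranking$measure)
  }, 0)
  expect_true(all(diff(ranks) <= 0))
})

test_that("single-feature accuracy ranking retains the top 10 of 32", {
  co <- generateCohort(cohortConfig(
    groupSizes = c("0" = 20, "0.5" = 10, "1" = 20), seed = 30))
  res <- rankBySingleFeatureAccuracy(co, "1v0", rounds = 5, iterations = 1,
                                     seed = 31)
  expect_s4_class(res, "ReductionResult")
  expect_equal(res@strategy, "expert_accuracy")
  expect_equal(nrow(res@ranking), 32)
  expect_length(res@retained, 10)
  expect_equal(res@retained, res@ranking$measure[1:10])
  expect_true(all(diff(res@ranking$score) <= 1e-12))
})

test_that("a perfectly separating feature ranks first with accuracy 1", {
  co <- plantedCohort(nPerGroup = 30, shift1 = 8, seed = 32,
                      measures = c("LDELTOTAL", "MMSCORE", "CLOCKSCOR",
                                   "AVTOTB"))
  res <- rankBySingleFeatureAccuracy(
    co, "1v0", measures = c("LDELTOTAL", "MMSCORE", "CLOCKSCOR", "AVTOTB"),
    rounds = 5, iterations = 2, top = 2, seed = 33)
  expect_equal(res@ranking$measure[1], "LDELTOTAL")
  expect_equal(res@ranking$score[1], 1.0)
})

test_that("pure-noise features score near chance accuracy", {
  co <- nullCohort(nPerGroup = 120, seed = 34,
                   measures = c("LDELTOTAL", "MMSCORE", "CLOCKSCOR"))
  res <- rankBySingleFeatureAccuracy(
    co, "1v0", measures = c("LDELTOTAL", "MMSCORE", "CLOCKSCOR"),
    rounds = 10, iterations = 10, top = 3, seed = 35)
  # 99% binomial band around 0.5 for n = 240 balanced subjects
  half <- 2.576 * sqrt(0.25 / 240)
  expect_true(all(abs(res@ranking$score - 0.5) < half))
})

test_that("fewer candidates than the cut-off retains all with a warning", {
  co <- nullCohort(nPerGroup = 15, seed = 36,
                   measures = c("LDELTOTAL", "MMSCORE"))
  expect_warning(
    res <- rankBySingleFeatureAccuracy(
      co, "1v0", measures = c("LDELTOTAL", "MMSCORE"),
      rounds = 5, iterations = 1, top = 10, seed = 37),
    "retaining all")
  expect_length(res@retained, 2)
})

test_that("reduction results serialize to TSV and JSON", {
  set.seed(38)
  Z <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, paste0("f", 1:6)))
  res <- reduceByFDR(Z, rep(c(0, 1), 20), fraction = 0.5)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  writeReductionTSV(res, tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$measure, res@ranking$measure)
  writeReductionJSON(res, js)
  payload <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(payload$retained, res@retained)
  expect_equal(payload$strategy, "fdr_filter")
})
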
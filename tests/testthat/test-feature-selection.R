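test_that("residualization reduces to group-mean subtraction on toys", {
  # intercept-only design: mean centering
  X <- cbind(p1 = c(1, 2, 3, 4))
  res <- residualize(X, design = matrix(1, 4, 1))
  expect_equal(unname(res[, 1]), c(-1.5, -0.5, 0.5, 1.5))
  # one binary covariate (0,0,1,1): within-group centering
  d <- cbind(1, c(0, 0, 1, 1))
  res2 <- residualize(X, design = d)
  expect_equal(unname(res2[, 1]), c(-0.5, 0.5, -0.5, 0.5))
})

test_that("residuals are orthogonal to every design column", {
  set.seed(14)
  for (i in 1:20) {
    n <- 60
    clin <- toyClinical(n, seed = i)
    X <- matrix(rnorm(n * 5), nrow = n,
                dimnames = list(NULL, paste0("P", 1:5)))
    res <- residualize(X, clin)
    D <- covariateDesign(clin)
    expect_lt(max(abs(crossprod(D, res))), 1e-8)
  }
})

test_that("residualization preserves ordering when covariates are orthogonal", {
  set.seed(15)
  n <- 2000
  clin <- toyClinical(n)
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "P1"))
  res <- residualize(X, clin)
  expect_gt(cor(res[, 1], X[, 1]), 0.99)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  n <- 30
  clin <- toyClinical(n)
  D <- covariateDesign(clin)
  D <- cbind(D, dup_age = D[, "age"])
  X <- matrix(rnorm(n), ncol = 1)
  expect_error(residualize(X, design = D), "dup_age")
})

test_that("the screen eliminates 25% and passes the top 20 forward", {
  co <- simulateCohort(cleanCohortConfig(n = 100, nProteins = 92,
                                         plantedOS = c(P001 = 1),
                                         seed = 19))
  X <- sampleMatrix(co)
  o <- survivalOutcome(co, "os")
  scr <- rfScreen(X, o, nRepeats = 2,
                  params = rsfParams(nEstimators = 60), seed = 5)
  expect_length(scr$retained, 92 - ceiling(0.25 * 92))  # 69
  expect_length(scr$top, 20)
  expect_true(all(scr$top %in% scr$retained))
  expect_setequal(scr$importance$rank, 1:92)
  expect_true("P001" %in% scr$top)
})

test_that("a planted protein survives screening in most seeded runs", {
  hits <- vapply(1:5, function(s) {
    co <- simulateCohort(cleanCohortConfig(n = 150, nProteins = 30,
                                           plantedOS = c(P003 = 1),
                                           seed = 300 + s))
    scr <- rfScreen(sampleMatrix(co), survivalOutcome(co, "os"),
                    nRepeats = 2, params = rsfParams(nEstimators = 80),
                    seed = s)
    "P003" %in% scr$top
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("tuning returns the best configuration by median CV concordance", {
  co <- simulateCohort(cleanCohortConfig(n = 90, nProteins = 6,
                                         plantedOS = c(P001 = 1),
                                         seed = 77))
  X <- sampleMatrix(co)
  o <- survivalOutcome(co, "os")
  # single-configuration grid: returned unchanged
  grid1 <- list(nEstimators = 30L, maxFeatures = 2L, minSamplesLeaf = 4L,
                minSamplesSplit = 8L)
  tr <- tuneRSF(X, o, grid = grid1, nCandidates = 3, nFolds = 3,
                nRepeats = 2, seed = 4)
  expect_equal(tr@bestParams$nEstimators, 30L)
  expect_equal(tr@bestParams$maxFeatures, 2L)
  # per-configuration distribution has nFolds x nRepeats entries
  expect_length(tr@cvC[[1]], 6)
  expect_equal(max(tr@candidates$median_c),
               tr@candidates$median_c[which.max(tr@candidates$median_c)])
})

test_that("cross-validation returns full distributions and honest optimism", {
  co <- simulateCohort(cleanCohortConfig(n = 80, nProteins = 5,
                                         plantedOS = c(P001 = 1),
                                         seed = 31))
  X <- sampleMatrix(co)
  o <- survivalOutcome(co, "os")
  cv <- crossvalRSF(X, o, rsfParams(nEstimators = 40, seed = 1),
                    nFolds = 4, nRepeats = 2, seed = 2)
  expect_length(cv$testC, 8)
  expect_length(cv$trainC, 8)
  expect_gte(cv$medianTrainC, cv$medianTestC)
  # degenerate single-leaf forest: constant risk, all credits 0.5
  cv0 <- crossvalRSF(X, o,
                     rsfParams(nEstimators = 5, minSamplesLeaf = 1,
                               minSamplesSplit = 10000, seed = 1),
                     nFolds = 4, nRepeats = 1, seed = 2)
  expect_true(all(cv0$testC == 0.5))
})

test_that("recursive feature elimination tracks the concordance curve", {
  co <- simulateCohort(cleanCohortConfig(n = 120, nProteins = 10,
                                         plantedOS = c(P002 = 1.2),
                                         seed = 41))
  X <- sampleMatrix(co)
  o <- survivalOutcome(co, "os")
  p <- rsfParams(nEstimators = 50, seed = 7)
  rfe <- recursiveFeatureElimination(X, o, p, nFolds = 3, nRepeats = 1,
                                     impRepeats = 2, seed = 3)
  expect_equal(nrow(rfe@curve), 10)
  expect_length(rfe@selectedSet, rfe@selectedSize)
  expect_true("P002" %in% rfe@selectedSet)
  best <- max(rfe@curve$median_test_c)
  expect_equal(rfe@curve$median_test_c[rfe@selectedSize], best)
  # ties break toward smaller k
  expect_true(all(rfe@curve$median_test_c[seq_len(rfe@selectedSize - 1)] <
                    best))
  # single protein: trivially selected
  rfe1 <- recursiveFeatureElimination(X[, "P002", drop = FALSE], o, p,
                                      nFolds = 3, nRepeats = 1,
                                      impRepeats = 1, seed = 3)
  expect_equal(rfe1@selectedSet, "P002")
  expect_equal(rfe1@selectedSize, 1L)
})

test_that("the RFE curve endpoint equals crossvalRSF on the full set", {
  co <- simulateCohort(cleanCohortConfig(n = 70, nProteins = 5,
                                         plantedOS = c(P001 = 1),
                                         seed = 51))
  X <- sampleMatrix(co)
  o <- survivalOutcome(co, "os")
  p <- rsfParams(nEstimators = 30, seed = 2)
  rfe <- recursiveFeatureElimination(X, o, p, nFolds = 3, nRepeats = 2,
                                     impRepeats = 1, seed = 6)
  cvFull <- crossvalRSF(X[, rfe@ranking], o, p, nFolds = 3, nRepeats = 2,
                        seed = 6)
  expect_equal(rfe@curve$median_test_c[5], cvFull$medianTestC)
})

test_that("rank concordance reports Spearman correlations and overlaps", {
  r1 <- setNames(1:5, paste0("P", 1:5))
  same <- rankConcordance(list(a = r1, b = r1))
  expect_equal(unname(same$spearman["a", "b"]), 1)
  rev2 <- setNames(5:1, paste0("P", 1:5))
  opp <- rankConcordance(list(a = r1, b = rev2))
  expect_equal(unname(opp$spearman["a", "b"]), -1)
  expect_error(rankConcordance(list(a = r1)), "two models")
  expect_error(rankConcordance(list(a = r1, b = setNames(1:2, c("X", "Y")))),
               "share no proteins")
  ov <- rankConcordance(list(a = r1, b = rev2), k = 2)$overlap
  expect_equal(ov$intersection, 0)
  expect_equal(ov$union, 4)
})
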
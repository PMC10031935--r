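test_that("Harrell's C reproduces hand-enumerated toys", {
  expect_equal(harrellC(data.frame(time = 1:4, event = 1L), c(4, 3, 2, 1)), 1)
  # times (1,2,3), risks (1,3,2): pairs (1,2),(1,3),(2,3); concordant only (2,3)
  expect_equal(harrellC(data.frame(time = 1:3, event = 1L), c(1, 3, 2)),
               1 / 3)
  expect_equal(harrellC(data.frame(time = 1:3, event = 1L), c(1, 1, 1)), 0.5)
  expect_error(harrellC(data.frame(time = 1:3, event = 0L), c(1, 2, 3)),
               "no comparable pair")
})

test_that("Harrell's C equals the pair-enumeration oracle on random instances", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(3:50, 1)
    time <- round(rexp(n, 0.1), 1) + 0.1
    event <- rbinom(n, 1, 0.7)
    risk <- sample(round(rnorm(n), 1), n)
    expected <- oracleHarrellC(time, event, risk)
    if (is.na(expected)) next
    expect_identical(harrellC(data.frame(time = time, event = event), risk),
                     expected)
  }
})

test_that("Harrell's C is invariant under strictly monotone risk transforms", {
  set.seed(7)
  time <- rexp(30) + 0.1
  event <- rbinom(30, 1, 0.6)
  event[1] <- 1L
  risk <- rnorm(30)
  o <- data.frame(time = time, event = event)
  expect_equal(harrellC(o, risk), harrellC(o, exp(risk)))
  expect_equal(harrellC(o, risk), harrellC(o, risk^3 + 5 * risk))
})

test_that("Nelson-Aalen matches hand tabulation", {
  # times (5,8,8,12), events (1,1,0,1): risk sets 4, 3, 1
  na <- nelsonAalen(data.frame(time = c(5, 8, 8, 12),
                               event = c(1, 1, 0, 1)))
  expect_equal(na$time, c(5, 8, 12))
  expect_equal(na$hazard, c(1 / 4, 1 / 4 + 1 / 3, 1 / 4 + 1 / 3 + 1))
  # no events -> identically zero
  expect_equal(nrow(nelsonAalen(data.frame(time = c(1, 2), event = 0L))), 0L)
  # single event -> H = 1
  expect_equal(nelsonAalen(data.frame(time = 3, event = 1L))$hazard, 1)
})

test_that("log-rank split statistic matches hand value and survdiff", {
  o <- data.frame(time = 1:4, event = 1L)
  # groups {1,2} vs {3,4}: (O-E) = 7/6, V = 17/36
  expect_equal(logrankSplitStat(o, c(1, 1, 0, 0)), (7 / 6)^2 / (17 / 36))
  # identical multisets -> 0
  o2 <- data.frame(time = c(1, 2, 1, 2), event = 1L)
  expect_equal(logrankSplitStat(o2, c(1, 1, 0, 0)), 0)

  set.seed(55)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    time <- round(rexp(n, 0.2), 2) + 0.01
    event <- rbinom(n, 1, 0.7)
    grp <- rbinom(n, 1, 0.5)
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(logrankSplitStat(data.frame(time = time, event = event),
                                  grp),
                 unname(ref$chisq), tolerance = 1e-10)
  }
})

test_that("RSF fits are reproducible and leaves partition the bootstrap", {
  co <- simulateCohort(cleanCohortConfig(n = 80, nProteins = 8,
                                         plantedOS = c(P001 = 0.8),
                                         seed = 12))
  X <- sampleMatrix(co)
  o <- survivalOutcome(co, "os")
  p <- rsfParams(nEstimators = 25, seed = 42)
  f1 <- fitRSF(X, o, p)
  f2 <- fitRSF(X, o, p)
  expect_identical(f1@trees, f2@trees)
  expect_identical(f1@inbag, f2@inbag)
  # grid is the distinct event times
  t <- as.numeric(o[, "time"])[as.integer(o[, "status"]) == 1]
  expect_identical(f1@grid, sort(unique(t)))
  # every tree's leaf CHF is non-decreasing
  for (tr in f1@trees[1:5]) {
    for (l in seq_len(nrow(tr$leafCHF)))
      expect_true(all(diff(tr$leafCHF[l, ]) >= -1e-12))
  }
})

test_that("a perfectly ordering protein drives OOB concordance above 0.9", {
  set.seed(33)
  n <- 200
  time <- sort(rexp(n, 0.05) + 0.1)
  X <- cbind(risk_marker = -time + rnorm(n, 0, 1e-6),
             matrix(rnorm(n * 9), nrow = n,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  o <- data.frame(time = time, event = 1L)
  f <- fitRSF(X, o, rsfParams(nEstimators = 100, seed = 5))
  cOOB <- harrellC(o, predictRisk(f, X, oob = TRUE))
  expect_gt(cOOB, 0.9)
})

test_that("pure-noise proteins give out-of-bag concordance near 0.5", {
  cs <- vapply(1:5, function(s) {
    co <- simulateCohort(cleanCohortConfig(n = 120, nProteins = 10,
                                           seed = 100 + s))
    X <- sampleMatrix(co)
    o <- survivalOutcome(co, "os")
    f <- fitRSF(X, o, rsfParams(nEstimators = 60, seed = s))
    harrellC(o, predictRisk(f, X, oob = TRUE))
  }, numeric(1))
  expect_true(all(cs > 0.4 & cs < 0.6))
})

test_that("predicted risk is the mean leaf cumulative hazard over the grid", {
  # depth-1 single tree: trace the one split by hand
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- rep(1L, 8)
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)  # late survivors have x = 1
  X <- cbind(marker = x)
  f <- fitRSF(X, data.frame(time = time, event = event),
              rsfParams(nEstimators = 1, maxFeatures = 1,
                        minSamplesLeaf = 1, minSamplesSplit = 2, seed = 1))
  tr <- f@trees[[1]]
  risk <- predictRisk(f, X)
  # samples routed to the same leaf share a score; leaf hazards ordered
  expect_true(length(unique(risk)) >= 2)
  # hand recomputation: route each sample, sum its leaf CHF over the grid
  routed <- vapply(seq_len(nrow(X)), function(i) {
    node <- 1
    while (tr$var[node] >= 0) {
      node <- if (X[i, tr$var[node] + 1] <= tr$thr[node])
        tr$left[node] + 1 else tr$right[node] + 1
    }
    mean(sum(tr$leafCHF[tr$leafRow[node] + 1, ]))
  }, numeric(1))
  expect_equal(unname(risk), routed)

  # single-leaf forest: identical scores
  f0 <- fitRSF(X, data.frame(time = time, event = event),
               rsfParams(nEstimators = 3, maxFeatures = 1,
                         minSamplesLeaf = 4, minSamplesSplit = 100,
                         seed = 2))
  expect_equal(length(unique(predictRisk(f0, X))), 1L)
})

test_that("permutation importance is exactly zero for unsplittable proteins", {
  co <- simulateCohort(cleanCohortConfig(n = 100, nProteins = 5,
                                         plantedOS = c(P001 = 1), seed = 9))
  X <- sampleMatrix(co)
  X <- cbind(X, constant = 5)  # constant column can never split
  o <- survivalOutcome(co, "os")
  f <- fitRSF(X, o, rsfParams(nEstimators = 40, seed = 3))
  imp <- permutationImportance(f, X, o, nRepeats = 3, seed = 11)
  expect_identical(imp$importance[imp$protein == "constant"], 0)
  # the sole informative protein dominates
  expect_equal(imp$protein[which.max(imp$importance)], "P001")
  # reproducible under a fixed seed
  imp2 <- permutationImportance(f, X, o, nRepeats = 3, seed = 11)
  expect_identical(imp$importance, imp2$importance)
})

test_that("rsf parameter invariants are enforced", {
  expect_error(rsfParams(minSamplesLeaf = 6, minSamplesSplit = 10),
               "2 \\* minSamplesLeaf")
  expect_error(rsfParams(nEstimators = 0), "positive")
  co <- simulateCohort(cleanCohortConfig(n = 30, nProteins = 3, seed = 2))
  X <- sampleMatrix(co)
  X[1, 1] <- NA
  expect_error(fitRSF(X, survivalOutcome(co, "os")), "NA")
})
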
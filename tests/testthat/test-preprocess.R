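test_that("sample exclusions retain exactly the available samples", {
  # 156 enrolled, 14 without serum, 5 QC failures, 1 insufficient -> 136
  manifest <- data.frame(
    sample_id = sprintf("S%03d", 1:156),
    status = c(rep("available", 136), rep("no_sample", 14),
               rep("qc_fail", 5), "insufficient_material"))
  res <- applySampleExclusions(manifest)
  expect_length(res$retained, 136)
  expect_equal(res$report@nSamplesIn, 156L)
  expect_equal(res$report@nSamplesOut, 136L)
  expect_equal(as.vector(table(res$report@removedSamples$reason)[
    c("no_sample", "qc_fail", "insufficient_material")]), c(14L, 5L, 1L))
})

test_that("all-available and empty manifests are handled", {
  all_ok <- data.frame(sample_id = c("a", "b"), status = "available")
  res <- applySampleExclusions(all_ok)
  expect_equal(res$retained, c("a", "b"))
  expect_equal(nrow(res$report@removedSamples), 0L)

  empty <- data.frame(sample_id = character(), status = character())
  res0 <- applySampleExclusions(empty)
  expect_length(res0$retained, 0)
  expect_equal(res0$report@nSamplesIn, 0L)

  bad <- data.frame(sample_id = "s1", status = "lost_in_mail")
  expect_error(applySampleExclusions(bad), "s1")
})

test_that("LOD filter removes proteins first, then samples, strictly above 15%", {
  # protein A: 2/10 samples below LOD (20% > 15%) -> removed
  m <- matrix(5, nrow = 3, ncol = 10,
              dimnames = list(c("A", "B", "C"), sprintf("s%02d", 1:10)))
  m["A", 1:2] <- 0
  x <- toyNPX(m, lod = c(1, 1, 1))
  res <- filterByLOD(x)
  expect_identical(rownames(res$retained), c("B", "C"))
  expect_equal(res$report@removedProteins$below_lod_fraction, 0.2)

  # exactly 15% is not removed (strict inequality)
  m2 <- matrix(5, nrow = 1, ncol = 20,
               dimnames = list("A", sprintf("s%02d", 1:20)))
  m2["A", 1:3] <- 0  # 3/20 = 15%
  res2 <- filterByLOD(toyNPX(m2, lod = 1))
  expect_identical(rownames(res2$retained), "A")
})

test_that("LOD filter counts match hand enumeration on a small toy", {
  # proteins x samples = 4 x 20: P4 below LOD in 4/20 (20%) -> removed;
  # then s20 below LOD in 2/3 of retained proteins -> removed;
  # P1, P2 at 1/20 (5%) stay
  m <- matrix(5, nrow = 4, ncol = 20,
              dimnames = list(paste0("P", 1:4), sprintf("s%02d", 1:20)))
  m["P4", 1:4] <- 0
  m["P1", 20] <- 0
  m["P2", 20] <- 0
  x <- toyNPX(m, lod = rep(1, 4))
  res <- filterByLOD(x)
  expect_identical(rownames(res$retained), c("P1", "P2", "P3"))
  expect_identical(colnames(res$retained), sprintf("s%02d", 1:19))
  expect_equal(res$report@removedProteins$below_lod_fraction, 0.2)
  expect_equal(res$report@removedSamples$below_lod_fraction, 2 / 3)
  expect_equal(res$report@nSamplesOut, 19L)
  expect_equal(res$report@nProteinsOut, 3L)
})

test_that("rescaling subtracts the LOD and censors deep below-LOD values", {
  # LOD 2.0, SD(LOD) 0.5: values (3.0, 1.8, 0.5) -> (1.0, -0.2, NA)
  m <- matrix(c(3.0, 1.8, 0.5), nrow = 1,
              dimnames = list("P1", c("s1", "s2", "s3")))
  x <- toyNPX(m, lod = 2.0, lodSD = 0.5)
  res <- rescaleAndCensor(x)
  out <- npxValues(res$retained)
  expect_equal(unname(out["P1", ]), c(1.0, -0.2, NA))
  expect_equal(res$report@nValuesRescaled, 2L)
  expect_equal(res$report@nValuesSetNA, 1L)

  # boundary: v = LOD -> 0; v = LOD - 3 SD -> NA
  m2 <- matrix(c(2.0, 0.5), nrow = 1, dimnames = list("P1", c("a", "b")))
  res2 <- rescaleAndCensor(toyNPX(m2, lod = 2.0, lodSD = 0.5))
  expect_equal(unname(npxValues(res2$retained)["P1", ]), c(0, NA))
})

test_that("rescaling preserves between-sample differences of observed values", {
  set.seed(8)
  m <- matrix(rnorm(50, mean = 6), nrow = 5)
  x <- toyNPX(m, lod = runif(5, 1, 2), lodSD = rep(0.2, 5))
  out <- npxValues(rescaleAndCensor(x)$retained)
  d0 <- m[, 2] - m[, 1]
  d1 <- out[, 2] - out[, 1]
  keep <- !is.na(d1)
  expect_equal(unname(d1[keep]), unname(d0[keep]))
})

test_that("kNN imputation matches hand-computed and brute-force neighbors", {
  # 6 samples, one NA in protein P2; other five values 1..5, k = 5:
  # all five others are the neighbors -> mean = 3
  m <- matrix(0, nrow = 2, ncol = 6,
              dimnames = list(c("P1", "P2"), paste0("s", 1:6)))
  m["P1", ] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  m["P2", ] <- c(NA, 1, 2, 3, 4, 5)
  x <- toyNPX(m, lod = c(-5, -5))
  res <- imputeKNN(x, k = 5)
  expect_equal(npxValues(res$retained)["P2", "s1"], 3.0)
  expect_equal(res$report@nValuesImputed, 1L)
  # observed values never altered
  expect_equal(npxValues(res$retained)["P2", -1], m["P2", -1])

  # 8-sample toy with two clusters: imputed value equals the mean over the
  # brute-force 3 nearest neighbors
  set.seed(3)
  M <- rbind(matrix(rnorm(12, 0, 0.1), nrow = 4),
             matrix(rnorm(12, 10, 0.1), nrow = 4))  # samples x proteins
  colnames(M) <- c("Pa", "Pb", "Pc")
  rownames(M) <- paste0("s", 1:8)
  M[1, "Pc"] <- NA
  d <- sapply(2:8, function(j) {
    sh <- !is.na(M[1, ]) & !is.na(M[j, ])
    sum((M[1, sh] - M[j, sh])^2) / sum(sh)
  })
  nb <- (2:8)[order(d)][1:3]
  expected <- mean(M[nb, "Pc"])
  x2 <- toyNPX(t(M), lod = rep(-50, 3))
  res2 <- imputeKNN(x2, k = 3)
  expect_equal(npxValues(res2$retained)["Pc", "s1"], expected)
})

test_that("imputation rejects impossible inputs and leaves no NA", {
  m <- matrix(c(1, NA, 2, 3), nrow = 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  expect_error(imputeKNN(toyNPX(m, lod = c(-9, -9)), k = 5), "k must be")
  mAll <- matrix(c(1, NA, 2, NA), nrow = 2,
                 dimnames = list(c("P1", "P2"), c("s1", "s2")))
  expect_error(imputeKNN(toyNPX(mAll, lod = c(-9, -9)), k = 1),
               "NA in all samples")
  # identity on complete matrices
  mOK <- matrix(rnorm(20), nrow = 4)
  x <- toyNPX(mOK, lod = rep(-9, 4))
  expect_equal(npxValues(imputeKNN(x, k = 2)$retained), npxValues(x))
})

test_that("full pipeline reconciles counts at every stage and ends NA-free", {
  co <- simulateCohort(cohortConfig(nSamples = 60, nProteins = 15,
                                    correlationBlocks = list(c(5, 0.5)),
                                    lodQuantile = 0.08, lodSD = 0.1,
                                    missingSampleFraction = 0.15, seed = 21))
  pp <- preprocessNPX(co)
  reps <- pp$reports
  expect_equal(reps$exclusions@nSamplesOut, reps$lodFilter@nSamplesIn)
  expect_equal(reps$lodFilter@nSamplesOut, reps$rescale@nSamplesIn)
  expect_equal(reps$lodFilter@nProteinsOut, reps$rescale@nProteinsIn)
  expect_equal(reps$rescale@nSamplesOut, reps$impute@nSamplesIn)
  expect_false(anyNA(npxValues(pp$retained)))
  expect_equal(reps$impute@nValuesImputed, reps$rescale@nValuesSetNA)
})
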
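test_that("middle-.8 interval interpolates order statistics", {
  expect_equal(middle80(1:11), c(2, 10))
  expect_equal(middle80(1:10), c(1.9, 9.1))
  expect_equal(middle80(rep(3.5, 6)), c(3.5, 3.5))
  expect_error(middle80(1), "at least 2")
})

test_that("bootstrap resampling is deterministic and class-balanced", {
  y <- rep(c(0, 1), c(66, 22))
  set.seed(99)
  a <- bootstrapResample(y)
  set.seed(99)
  b <- bootstrapResample(y)
  expect_identical(as.integer(a), as.integer(b))
  expect_length(a, 88L)
  expect_true(all(a >= 1 & a <= 88))
  expect_gte(sum(y[a] == 1), 2)
  expect_gte(sum(y[a] == 0), 2)
})

test_that("bootstrap inclusion rate approaches 1 - 1/e", {
  y <- rep(c(0, 1), 44)
  set.seed(123)
  frac <- replicate(1000, length(unique(bootstrapResample(y))) / 88)
  expect_lt(abs(mean(frac) - (1 - exp(-1))), 0.02)
})

test_that("pathologically imbalanced outcomes exhaust the redraw cap", {
  y <- c(1, rep(0, 87))
  set.seed(1)
  expect_error(bootstrapResample(y, maxRedraws = 50), "pathological")
})

test_that("stability accounting matches hand enumeration of replicate sets", {
  sets <- list(c("a", "b"), c("a", "b"), c("a", "c"))
  dist <- enetBoot:::.jaccardDistribution(sets, c("a", "b"),
                                          BootstrapConfig(B = 3))
  expect_equal(sort(dist$values), sort(c(1, 1 / 3, 1 / 3)))
  expect_equal(dist$point, 5 / 9)
  expect_identical(dist$emptyPairs, 0L)

  # empty sets: empty-empty excluded and counted, empty-vs-nonempty scores 0
  dist2 <- enetBoot:::.jaccardDistribution(
    list(character(0), character(0), "a"), character(0), BootstrapConfig(B = 3))
  expect_identical(dist2$emptyPairs, 1L)
  expect_equal(dist2$values, c(0, 0))

  # original-pairing variant compares each replicate to the full-data set
  dist3 <- enetBoot:::.jaccardDistribution(
    sets, c("a", "b"), BootstrapConfig(B = 3, pairing = "original"))
  expect_equal(sort(dist3$values), sort(c(1, 1, 1 / 3)))
})

test_that("validation reports satisfy their exact identities and reproduce bitwise", {
  sim <- signalDataset(n = 70, p = 30, seed = 21)
  bc <- BootstrapConfig(B = 20, seed = 77)
  v1 <- optimismValidate(dataset(sim), bootConfig = bc)
  for (m in c("brier", "concordance")) {
    expect_equal(v1@corrected[[m]], v1@apparent[[m]] - v1@optimism[[m]],
                 tolerance = 1e-12)
    iv <- v1@intervals[[m]]
    expect_lte(iv[1], iv[2])
    # per-replicate corrected values average to the corrected point estimate
    expect_equal(mean(v1@replicates[[paste0(m, "_corrected")]]),
                 unname(v1@corrected[m]), tolerance = 1e-12)
  }
  expect_true(all(v1@calibration$lower80 <= v1@calibration$upper80 + 1e-12))
  expect_true(all(v1@calibration$observed_corrected >= 0 &
                  v1@calibration$observed_corrected <= 1))

  v2 <- optimismValidate(dataset(sim), bootConfig = bc)
  expect_identical(v1@replicates, v2@replicates)
  expect_identical(v1@calibration, v2@calibration)
  expect_identical(v1@corrected, v2@corrected)
})

test_that("the full tuning procedure is refit inside every replicate", {
  sim <- signalDataset(n = 90, p = 60, nSignal = 8, effectSize = 1.2, seed = 5)
  st <- stabilityAnalysis(dataset(sim), bootConfig = BootstrapConfig(B = 25, seed = 8))
  # replicate selected-set sizes vary when tuning is redone per replicate
  expect_gt(length(unique(st@replicateSetSizes)), 1L)
})

test_that("selection and co-selection probabilities obey their bounds", {
  sim <- signalDataset(n = 80, p = 40, seed = 33)
  bc <- BootstrapConfig(B = 20, seed = 3)
  st <- stabilityAnalysis(dataset(sim), bootConfig = bc)
  p <- st@selectionProbability
  expect_true(all(p >= 0 & p <= 1))
  cs <- st@coSelection
  if (length(cs)) {
    g <- rownames(cs)
    expect_equal(unname(diag(cs)), unname(p[g]), tolerance = 1e-12)
    expect_true(all(cs <= outer(p[g], p[g], pmin) + 1e-12))
    expect_true(all(abs(cs - t(cs)) < 1e-12))
  }
  expect_identical(st@B, bc@B)
  expect_identical(st@seed, bc@seed)

  st2 <- stabilityAnalysis(dataset(sim), bootConfig = bc)
  expect_identical(st@selectionProbability, st2@selectionProbability)
  expect_identical(st@jaccardValues, st2@jaccardValues)
})

test_that("all-null replicate selections leave stability undefined but reported", {
  sim <- simulateDataset(SimulationConfig(n = 60, p = 10, nSignal = 0, seed = 2))
  # a two-point path pinned near lambda_max never selects any gene
  mc <- ElasticNetConfig(nLambda = 2, lambdaMinRatio = 0.99)
  st <- stabilityAnalysis(dataset(sim), modelConfig = mc,
                          bootConfig = BootstrapConfig(B = 10, seed = 4))
  expect_true(all(st@selectionProbability == 0))
  expect_true(is.na(st@stabilityPoint))
  expect_true(is.na(st@expectedOverlap))
  expect_identical(st@emptyPairsExcluded, 45L)  # all choose(10, 2) pairs
  expect_length(st@jaccardValues, 0L)
})
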
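test_that("the null model is the analytic intercept-only fit", {
  y <- c(rep(1, 22), rep(0, 66))
  fit <- fitNullModel(y)
  expect_equal(fit@intercept, log(0.25 / 0.75), tolerance = 1e-12)
  expect_identical(fit@k, 0L)
  expect_equal(fit@aicPrime, 0)
  expect_equal(unname(predictProbabilities(fit, matrix(rnorm(5 * 0), 5, 0))),
               rep(0.25, 5), tolerance = 1e-12)

  expect_equal(fitNullModel(c(0, 1))@intercept, 0)

  y10 <- c(rep(1, 3), rep(0, 7))
  expect_equal(fitNullModel(y10)@loglik, 3 * log(0.3) + 7 * log(0.7),
               tolerance = 1e-12)

  expect_error(fitNullModel(rep(1, 10)), "both")
})

test_that("the modified Akaike criterion follows its closed form", {
  expect_equal(aicPrime(-50, -50, 0), 0)
  expect_equal(aicPrime(-40, -50, 10), 0)
  expect_equal(aicPrime(-30, -50, 5), 30)
  expect_error(aicPrime(-30, -50, -1), "nonnegative")
  expect_error(aicPrime(-60, -50, 2), "nest")
})

test_that("the largest penalty gives the null fit, and the criterion argmax matches a brute-force scan", {
  sim <- signalDataset()
  path <- fitPenaltyPath(dataset(sim))
  first <- path@fits[[1]]
  expect_identical(first@k, 0L)
  expect_equal(first@aicPrime, 0)
  # lambda_max predicts the constant prevalence for every sample
  prev <- mean(outcome(sim))
  pred <- predictProbabilities(first, dataset(sim))
  expect_equal(unname(pred), rep(prev, length(pred)), tolerance = 1e-6)

  expect_true(all(diff(path@lambdas) < 0))
  expect_identical(path@selectedIndex, aicArgmaxEnum(path))
  # log-likelihood never drops below the intercept-only maximum on the path
  ll0 <- first@nullLoglik
  expect_true(all(vapply(path@fits, function(f) f@loglik >= ll0 - 1e-8,
                         logical(1))))
})

test_that("the selected model recovers true signal genes on strong-signal data", {
  sim <- simulateDataset(SimulationConfig(n = 300, p = 100, nSignal = 10,
                                          effectSize = 1.0, seed = 9))
  sel <- selectByCriterion(fitPenaltyPath(dataset(sim)))
  expect_gt(length(intersect(sel$genes, sim@trueSupport)), 0)
  expect_identical(sel$genes, selectedGenes(sel$fit))
  expect_identical(length(sel$genes), as.integer(sel$fit@k))
})

test_that("duplicated predictor columns receive equal coefficients along the path", {
  sim <- signalDataset(n = 80, p = 20, seed = 11)
  x <- foldChanges(dataset(sim))
  x <- cbind(x, dup = x[, 1])
  colnames(x)[ncol(x)] <- "dup"
  path <- fitPenaltyPath(x, outcome(sim), ElasticNetConfig(tol = 1e-14))
  gaps <- vapply(path@fits, function(f) {
    abs(unname(f@coefficients["gene1"]) - unname(f@coefficients["dup"]))
  }, numeric(1))
  # the strictly convex ridge component forces exact equality at the
  # optimum; coordinate descent resolves this flat direction only to
  # solver precision, so assert at that level
  expect_lt(max(gaps), 1e-3)
  expect_lt(median(gaps), 1e-5)
})

test_that("rescaling a gene's column rescales its coefficient without changing predictions", {
  sim <- signalDataset(n = 100, p = 30, seed = 13)
  x <- foldChanges(dataset(sim))
  y <- outcome(sim)
  cfg <- ElasticNetConfig(tol = 1e-12)
  c0 <- 4
  x2 <- x
  x2[, "gene1"] <- x2[, "gene1"] * c0
  s1 <- selectByCriterion(fitPenaltyPath(x, y, cfg))
  s2 <- selectByCriterion(fitPenaltyPath(x2, y, cfg))
  expect_equal(unname(s2$fit@coefficients["gene1"]),
               unname(s1$fit@coefficients["gene1"]) / c0, tolerance = 1e-6)
  expect_equal(predictProbabilities(s2$fit, x2), predictProbabilities(s1$fit, x),
               tolerance = 1e-6)
})

test_that("criterion ties break toward the larger penalty", {
  # construct fits directly: equal criterion at lambda 0.5 and 0.1
  f1 <- methods::new("ModelFit", intercept = 0, coefficients = c(gene1 = 0),
                     lambda = 0.5, k = 0L, loglik = -10, nullLoglik = -10,
                     aicPrime = 0, converged = TRUE)
  f2 <- methods::new("ModelFit", intercept = 0, coefficients = c(gene1 = 1),
                     lambda = 0.1, k = 1L, loglik = -9, nullLoglik = -10,
                     aicPrime = 0, converged = TRUE)
  path <- methods::new("PenaltyPath", lambdas = c(0.5, 0.1), fits = list(f1, f2),
                       selectedIndex = 1L, criterion = "aic_prime")
  sel <- selectByCriterion(path)
  expect_equal(sel$fit@lambda, 0.5)
  expect_identical(sel$genes, character(0))
})

test_that("the small-sample criterion penalizes large models harder", {
  sim <- signalDataset(n = 60, p = 40, seed = 17)
  x <- foldChanges(dataset(sim)); y <- outcome(sim)
  selA <- selectByCriterion(fitPenaltyPath(x, y), n = length(y))
  cfgC <- ElasticNetConfig(criterion = "aicc_prime")
  selC <- selectByCriterion(fitPenaltyPath(x, y, cfgC), cfgC, n = length(y))
  expect_lte(selC$fit@k, selA$fit@k)
  # aicc is -Inf once k reaches n - 1
  expect_identical(enetBoot:::.aiccPrime(-1, -10, 59L, 60L), -Inf)
})

test_that("predicted probabilities follow the inverse logit", {
  fit <- methods::new("ModelFit", intercept = 0, coefficients = c(g1 = 0),
                      lambda = 1, k = 0L, loglik = -1, nullLoglik = -1,
                      aicPrime = 0, converged = TRUE)
  x <- matrix(rnorm(4), 4, 1, dimnames = list(NULL, "g1"))
  expect_equal(unname(predictProbabilities(fit, x)), rep(0.5, 4))

  fit@intercept <- log(3)
  expect_equal(unname(predictProbabilities(fit, x)), rep(0.75, 4))

  fit2 <- methods::new("ModelFit", intercept = 0, coefficients = c(g1 = 1),
                       lambda = 1, k = 1L, loglik = -1, nullLoglik = -1,
                       aicPrime = -2, converged = TRUE)
  expect_equal(unname(predictProbabilities(fit2, matrix(2, 1, 1,
                                                        dimnames = list(NULL, "g1")))),
               1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_error(predictProbabilities(fit2, matrix(0, 1, 2)), "mismatch")
})

test_that("invalid model inputs are rejected", {
  sim <- signalDataset(n = 20, p = 10, seed = 3)
  x <- foldChanges(dataset(sim)); y <- outcome(sim)
  x[1, 1] <- NA
  expect_error(fitPenaltyPath(x, y), "non-finite")
  expect_error(fitPenaltyPath(foldChanges(dataset(sim)), rep(1, 20)), "both")
  expect_error(fitPenaltyPath(foldChanges(dataset(sim))[1:3, ], y[1:3]),
               "at least 4")
})
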
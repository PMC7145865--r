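test_that("path fitting recovers an exact linear system", {
  # m = 0.5 x + disturbance, y = 0.4 m + 0.2 x exactly (noiseless outcome)
  set.seed(1)
  n <- 200
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.4 * m + 0.2 * x
  paths <- fitPaths(x, m, y, standardize = FALSE)
  expect_equal(unname(paths["b"]), 0.4, tolerance = 1e-10)
  expect_equal(unname(paths["cPrime"]), 0.2, tolerance = 1e-10)
  expect_equal(unname(paths["a"]), unname(coef(lm(m ~ x))[2]), tolerance = 1e-10)
  # m an exact multiple of x is a collinear design
  expect_error(fitPaths(x, 0.5 * x, y, standardize = FALSE), "collinear")
})

test_that("c = cPrime + a*b holds exactly for any input", {
  set.seed(2)
  for (rep in 1:20) {
    n <- 60
    covs <- if (rep %% 2) matrix(rnorm(2 * n), n, 2) else NULL
    x <- rnorm(n); m <- 0.3 * x + rnorm(n)
    y <- 0.2 * x + 0.4 * m + rnorm(n)
    p <- fitPaths(x, m, y, covs)
    expect_equal(unname(p["c"]), unname(p["cPrime"] + p["a"] * p["b"]),
                 tolerance = 1e-10)
  }
})

test_that("null generating model yields near-zero paths", {
  set.seed(3)
  n <- 2000
  p <- fitPaths(rnorm(n), rnorm(n), rnorm(n))
  expect_true(all(abs(p) < 3 / sqrt(n) * 1.5))
})

test_that("bootstrap recovers a planted indirect effect at large n", {
  set.seed(4)
  n <- 2000
  x <- rnorm(n)
  m <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  y <- 0.2 * x + 0.4 * m + sqrt(1 - (0.04 + 0.16 + 2 * 0.5 * 0.4 * 0.2)) * rnorm(n)
  res <- bootstrapIndirect(x, m, y, nBoot = 1000, seed = 5)
  expect_lt(abs(indirectEffect(res) - 0.20), 0.05)
  expect_true(isSignificant(res))
  expect_lte(res@ciLow, indirectEffect(res))
})

test_that("bias correction reduces to the percentile CI for symmetric bootstraps", {
  set.seed(6)
  n <- 400
  x <- rnorm(n); m <- 0.4 * x + rnorm(n); y <- 0.3 * m + rnorm(n)
  bc <- bootstrapIndirect(x, m, y, nBoot = 2000, method = "bias_corrected", seed = 7)
  pc <- bootstrapIndirect(x, m, y, nBoot = 2000, method = "percentile", seed = 7)
  # identical resamples (same seed); if the median matched the point
  # estimate exactly, z0 = 0 and the intervals coincide; here assert the
  # forced algebraic behavior on the actual z0
  expect_identical(bc@bootEstimates, pc@bootEstimates)
  probs <- pnorm(2 * bc@z0 + qnorm(c(0.025, 0.975)))
  expect_equal(c(bc@ciLow, bc@ciHigh),
               unname(quantile(pc@bootEstimates, probs, names = FALSE)))
  # z0 = 0 exactly when half the mass is below the point estimate: force it
  ab <- pc@bootEstimates
  point <- indirectEffect(pc)
  propBelow <- mean(ab < point) + 0.5 * mean(ab == point)
  if (abs(propBelow - 0.5) < 1e-12) expect_identical(bc@ciLow, pc@ciLow)
  # percentile CI brackets the point estimate
  expect_lte(pc@ciLow, point)
  expect_gte(pc@ciHigh, point)
})

test_that("bootstrap mean approaches the point estimate as nBoot grows", {
  set.seed(8)
  n <- 300
  x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.4 * m + 0.1 * x + rnorm(n)
  res <- bootstrapIndirect(x, m, y, nBoot = 20000, seed = 9)
  expect_lt(abs(mean(res@bootEstimates) - indirectEffect(res)), 0.01)
})

test_that("covariate-adjusted bootstrap agrees with the plain route when
          covariates are pure noise", {
  set.seed(10)
  n <- 500
  x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.4 * m + rnorm(n)
  covs <- matrix(rnorm(n), n, 1)
  plain <- bootstrapIndirect(x, m, y, nBoot = 500, seed = 11)
  adj <- bootstrapIndirect(x, m, y, covs, nBoot = 500, seed = 11)
  expect_lt(abs(indirectEffect(plain) - indirectEffect(adj)), 0.02)
  expect_lt(abs(plain@ciLow - adj@ciLow), 0.05)
  expect_lt(abs(plain@ciHigh - adj@ciHigh), 0.05)
})

test_that("CI bounds are monotone in the confidence level and runs are
          deterministic given the seed", {
  set.seed(12)
  n <- 250
  x <- rnorm(n); m <- 0.4 * x + rnorm(n); y <- 0.3 * m + rnorm(n)
  r90 <- bootstrapIndirect(x, m, y, nBoot = 1000, ciLevel = 0.90, seed = 13)
  r99 <- bootstrapIndirect(x, m, y, nBoot = 1000, ciLevel = 0.99, seed = 13)
  expect_lte(r99@ciLow, r90@ciLow)
  expect_gte(r99@ciHigh, r90@ciHigh)
  again <- bootstrapIndirect(x, m, y, nBoot = 1000, ciLevel = 0.90, seed = 13)
  expect_identical(r90@bootEstimates, again@bootEstimates)
  expect_identical(c(r90@ciLow, r90@ciHigh), c(again@ciLow, again@ciHigh))
  expect_error(bootstrapIndirect(x, m, y, nBoot = 100, seed = 1), "200")
})

test_that("the two study models fit on a cohort with a planted VAN mediator", {
  spec <- tinySpec(nSubjects = 150L, tPoints = 150L,
                   partitionSizes = c(VAN = 5L, DAN = 4L, VN = 4L),
                   mediationCoeffs = c(a = 0.6, b = 0.5, cPrime = 0.2),
                   nuisanceLoadings = c(ageY = 0, sexY = 0, stressX = 0.3))
  ce <- profileCohort(simulateCohort(spec), defaultPartition(networkSizes(spec)))
  beh <- simulateBehavior(spec, mValues = connectivityValues(ce)["within_VAN", ])
  SummarizedExperiment::colData(ce) <- S4Vectors::DataFrame(
    beh, row.names = beh$subject_id)
  # a null dot-probe arm: shifts at zero
  trials <- simulateDotProbe(dotProbeSpec(nSubjects = 150, seed = 44))
  scores <- scoreCohort(filterTrials(trials), emotions = "NS")
  fits <- runMediationModels(ce, biasScores = scores, nBoot = 500, seed = 15)
  expect_named(fits, c("van", "sad_bias"))
  expect_true(isSignificant(fits$van))
  expect_false(isSignificant(fits$sad_bias))
  expect_error(runMediationModels(ce, mediatorMeasure = "within_XX"), "within_XX")
})
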
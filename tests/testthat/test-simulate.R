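test_that("cohort spec validation rejects impossible covariance structures", {
  # strongly negative between-block correlation of big blocks is not PD
  expect_error(cohortSpec(nSubjects = 5, tPoints = 50,
                          partitionSizes = c(A = 10L, B = 10L, C = 10L),
                          withinTargets = 0.1, betweenTargets = -0.5),
               "positive definite")
  expect_error(cohortSpec(nSubjects = 5, tPoints = 50,
                          partitionSizes = c(A = 3L), withinTargets = 1.2),
               "\\[0, 1\\)")
  # planted coefficients implying outcome R^2 >= 1 are rejected
  expect_error(cohortSpec(mediationCoeffs = c(a = 0.9, b = 0.9, cPrime = 0.9)),
               "R\\^2")
})

test_that("simulated time series realize the specified block correlations", {
  # independent nodes: mean off-diagonal correlation near 0
  spec0 <- tinySpec(nSubjects = 1L, tPoints = 2000L, withinTargets = 0,
                    betweenTargets = 0, perturbSd = 0)
  A0 <- correlationMatrix(simulateTimeSeries(spec0, 1))
  off0 <- A0[upper.tri(A0)]
  expect_lt(abs(mean(off0)), 3 / sqrt(2000))
  # one 10-node network at rho = 0.5, T = 2000: mean within-block
  # correlation within +/- 0.05 of target (Fisher-z SE ~ 1/sqrt(T-3))
  spec5 <- cohortSpec(nSubjects = 1L, tPoints = 2000L,
                      partitionSizes = c(NET = 10L), withinTargets = 0.5,
                      betweenTargets = 0, perturbSd = 0, seed = 21L)
  A5 <- correlationMatrix(simulateTimeSeries(spec5, 1))
  expect_lt(abs(mean(A5[upper.tri(A5)]) - 0.5), 0.05)
})

test_that("the time-series generator is deterministic given (seed, subject)", {
  spec <- tinySpec()
  a <- simulateTimeSeries(spec, 3)
  b <- simulateTimeSeries(spec, 3)
  expect_identical(a, b)
  expect_false(identical(simulateTimeSeries(spec, 2), a))
  # and invariant to calls for other subjects in between
  full <- simulateCohort(spec)
  expect_identical(full$S003, a)
})

test_that("behavior generator plants the requested mediation structure", {
  # null model: X, M, Y mutually uncorrelated within 3/sqrt(n)
  spec0 <- tinySpec(nSubjects = 2000L,
                    mediationCoeffs = c(a = 0, b = 0, cPrime = 0),
                    nuisanceLoadings = c(ageY = 0, sexY = 0, stressX = 0))
  b0 <- simulateBehavior(spec0)
  lat <- attr(b0, "latent")
  expect_lt(abs(cor(lat$x, lat$m)), 3 / sqrt(2000))
  expect_lt(abs(cor(lat$x, lat$y)), 3 / sqrt(2000))
  expect_lt(abs(cor(lat$m, lat$y)), 3 / sqrt(2000))
  # large-sample recovery of planted paths by OLS (closed-form oracle:
  # regression on the generating model recovers a, b, cPrime)
  spec <- tinySpec(nSubjects = 5000L,
                   mediationCoeffs = c(a = 0.5, b = 0.4, cPrime = 0.2),
                   nuisanceLoadings = c(ageY = 0, sexY = 0, stressX = 0))
  be <- simulateBehavior(spec)
  paths <- fitPaths(be$els, attr(be, "latent")$m, be$depression)
  expect_lt(abs(paths[["a"]] - 0.5), 0.05)
  expect_lt(abs(paths[["b"]] - 0.4), 0.05)
  expect_lt(abs(paths[["cPrime"]] - 0.2), 0.05)
  # determinism
  expect_identical(simulateBehavior(spec), be)
})

test_that("behavior couples the exposure to a supplied realized mediator", {
  spec <- tinySpec(nSubjects = 3000L,
                   mediationCoeffs = c(a = 0.6, b = 0.3, cPrime = 0.1))
  m <- rnorm(3000, mean = 5, sd = 2)
  be <- simulateBehavior(spec, mValues = m)
  expect_lt(abs(cor(be$els, m) - 0.6), 0.05)
  expect_equal(attr(be, "paths")[["a"]], cor(attr(be, "latent")$x, scale(m)[, 1]))
  expect_error(simulateBehavior(spec, mValues = 1:5), "length")
})

test_that("behavioral table has the documented demographics", {
  be <- simulateBehavior(tinySpec(nSubjects = 4000L))
  expect_true(all(be$age >= 16 & be$age <= 26))
  expect_lt(abs(mean(be$sex) - 157 / 528), 0.03)
  expect_lt(abs(mean(be$els) - 37.35), 1)
  expect_lt(abs(sd(be$els) - 8.34), 0.5)
})

test_that("dot-probe generator honors the task design and plants shifts", {
  sp <- dotProbeSpec(nSubjects = 2, seed = 5)
  tr <- simulateDotProbe(sp)
  # 2 blocks of 151 trials: 40 + 37 + 37 + 37 per block
  expect_identical(unname(table(tr$subject_id)[1]), 302L)
  counts <- table(tr$condition[tr$subject_id == "S001" & tr$block == 1])
  expect_identical(as.vector(counts[c("NH", "NS", "NA", "NF")]),
                   c(40L, 37L, 37L, 37L))
  expect_true(all(tr$rt_ms > 0))
  # noiseless +20 ms sad shift propagates exactly through the scoring identity
  spN <- dotProbeSpec(nSubjects = 3, biasShiftMs = c(NH = 0, NS = 20, "NA" = 0, NF = 0),
                      biasSdMs = 0, rtNoiseSdMs = 0, errorRate = 0, seed = 6)
  trN <- simulateDotProbe(spN)
  sc <- scoreCohort(trN, emotions = c("NS", "NH"))
  expect_equal(sc$bias_ms[sc$emotion == "NS"], rep(20, 3))
  expect_equal(sc$bias_ms[sc$emotion == "NH"], rep(0, 3))
  # zero-shift generator: cohort-mean bias within 3 SE of 0
  sp0 <- dotProbeSpec(nSubjects = 40, biasShiftMs = 0, biasSdMs = 0,
                      rtNoiseSdMs = 60, errorRate = 0, seed = 7)
  sc0 <- biasScore(simulateDotProbe(sp0), "NS")
  se <- sd(sc0$bias_ms) / sqrt(nrow(sc0))
  expect_lt(abs(mean(sc0$bias_ms)), 3 * se)
  # determinism
  expect_identical(simulateDotProbe(sp), tr)
})
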
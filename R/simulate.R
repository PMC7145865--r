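## Synthetic-data generator: block-covariance Gaussian ROI time series,
## behavioral tables with a planted X -> M -> Y mediation structure, and
## dot-probe trial logs with per-emotion bias shifts.

#' Standard 227-node, 10-network partition sizes
#'
#' Node counts of the ten named resting-state systems used throughout the
#' package (DMN, SN, FPN, CON, SMN, VN, VAN, DAN, AN, SUB), matching the
#' community sizes of the Power-264 parcellation restricted to these ten
#' systems (227 nodes in total).
#'
#' @return named integer vector summing to 227.
#' @export
powerPartitionSizes <- function() {
  c(DMN = 58L, SN = 18L, FPN = 25L, CON = 14L, SMN = 35L,
    VN = 31L, VAN = 9L, DAN = 11L, AN = 13L, SUB = 13L)
}

#' Build a NetworkPartition from partition sizes
#'
#' @param sizes named integer vector of nodes per network; defaults to
#'   [powerPartitionSizes()].
#' @return a [NetworkPartition-class] with node ids `ROI001, ROI002, ...`.
#' @export
defaultPartition <- function(sizes = powerPartitionSizes()) {
  NetworkPartition(sprintf("ROI%03d", seq_len(sum(sizes))),
                   rep(names(sizes), sizes), networkOrder = names(sizes))
}

#' Construct a CohortSpec
#'
#' Defaults emulate the primary study conditions: a college cohort measured
#' at rest for 230 retained volumes over the 227-node, 10-network partition,
#' with moderate within-network coupling, weak between-network coupling, and
#' a detectable planted mediation (a = 0.5, b = 0.4, c' = 0.2 standardized).
#'
#' @param nSubjects number of subjects (default 300).
#' @param tPoints time points per subject (default 230, i.e. 8 min at
#'   TR = 2 s minus 10 discarded volumes).
#' @param partitionSizes named integer vector of nodes per network.
#' @param withinTargets per-network target within-block correlation in
#'   `[0, 1)`; a scalar is recycled.
#' @param betweenTargets between-block target correlation; a scalar, or a
#'   symmetric K x K matrix for pair-specific targets.
#' @param mediationCoeffs numeric `c(a, b, cPrime)` standardized planted
#'   paths.
#' @param noiseSd outcome disturbance SD, or `NA` to auto-scale the outcome
#'   to unit variance (so planted paths are exactly the standardized
#'   coefficients).
#' @param perturbSd SD of per-subject perturbation of connectivity targets.
#' @param nuisanceLoadings numeric `c(ageY, sexY, stressX)`.
#' @param seed integer master seed.
#' @return a validated [CohortSpec-class]; construction fails if the implied
#'   block covariance is not positive definite.
#' @examples
#' spec <- cohortSpec(nSubjects = 10, tPoints = 50, seed = 1)
#' @export
cohortSpec <- function(nSubjects = 300L, tPoints = 230L,
                       partitionSizes = powerPartitionSizes(),
                       withinTargets = 0.25, betweenTargets = 0.08,
                       mediationCoeffs = c(a = 0.5, b = 0.4, cPrime = 0.2),
                       noiseSd = NA_real_, perturbSd = 0.05,
                       nuisanceLoadings = c(ageY = 0.1, sexY = 0.1, stressX = 0.3),
                       seed = 1L) {
  K <- length(partitionSizes)
  nm <- names(partitionSizes)
  if (length(withinTargets) == 1L)
    withinTargets <- stats::setNames(rep(withinTargets, K), nm)
  else if (is.null(names(withinTargets))) names(withinTargets) <- nm
  withinTargets <- withinTargets[nm]
  if (!is.matrix(betweenTargets)) {
    if (length(betweenTargets) != 1L)
      .stopf("betweenTargets must be a scalar or a K x K matrix")
    betweenTargets <- matrix(betweenTargets, K, K, dimnames = list(nm, nm))
  }
  diag(betweenTargets) <- 0
  co <- mediationCoeffs
  if (is.null(names(co))) names(co) <- c("a", "b", "cPrime")
  new("CohortSpec",
      nSubjects = as.integer(nSubjects), tPoints = as.integer(tPoints),
      partitionSizes = stats::setNames(as.integer(partitionSizes), nm),
      withinTargets = withinTargets, betweenTargets = betweenTargets,
      mediationCoeffs = co[c("a", "b", "cPrime")],
      noiseSd = as.numeric(noiseSd), perturbSd = as.numeric(perturbSd),
      nuisanceLoadings = nuisanceLoadings[c("ageY", "sexY", "stressX")],
      seed = as.integer(seed))
}

# per-subject connectivity targets: spec targets perturbed by Normal noise,
# truncated to the valid range, with positive definiteness re-checked (the
# between block is shrunk toward zero if a draw lands outside the PD cone)
.subjectTargets <- function(spec, subjectIndex) {
  K <- length(spec@partitionSizes)
  w <- pmin(pmax(spec@withinTargets + stats::rnorm(K, 0, spec@perturbSd), 0), 0.95)
  B <- spec@betweenTargets
  up <- upper.tri(B)
  B[up] <- pmin(pmax(B[up] + stats::rnorm(sum(up), 0, spec@perturbSd), -0.9), 0.9)
  B[lower.tri(B)] <- t(B)[lower.tri(B)]
  for (shrink in 0:25) {
    ev <- .blockEigen(spec@partitionSizes, w, B)
    if (min(ev) > 1e-10) return(list(within = w, between = B))
    B <- B * 0.9
  }
  .stopf("subject %d: perturbed block covariance not positive definite for networks %s",
         subjectIndex, paste(names(spec@partitionSizes), collapse = ", "))
}

#' Simulate one subject's ROI time-series matrix
#'
#' Draws a zero-mean multivariate normal T x N matrix whose correlation
#' matrix has compound-symmetric within-network blocks at the subject's
#' within-network targets and constant between-network blocks at the
#' between-network targets. Per-subject targets are the spec targets
#' perturbed by `Normal(0, perturbSd)` (truncated to the valid range), which
#' creates the inter-subject variance in true connectivity that the
#' brain-behavior analyses rely on. Deterministic given
#' `(spec@seed, subjectIndex)`.
#'
#' @param spec a [CohortSpec-class].
#' @param subjectIndex subject number in `1:nSubjects`.
#' @return T x N numeric matrix with node-id column names and a
#'   `subject_id` attribute.
#' @export
simulateTimeSeries <- function(spec, subjectIndex) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  if (subjectIndex < 1L || subjectIndex > spec@nSubjects)
    .stopf("subjectIndex must lie in 1:%d", spec@nSubjects)
  withSeed(childSeed(spec@seed, 1000L + subjectIndex), {
    tg <- .subjectTargets(spec, subjectIndex)
    memb <- rep(seq_along(spec@partitionSizes), spec@partitionSizes)
    N <- sum(spec@partitionSizes)
    Tn <- spec@tPoints
    R <- tg$between
    diag(R) <- tg$within
    # when the K x K target matrix R is itself PD, Sigma = diag(1 - w) +
    # U R U' and the draw reduces to K shared network factors plus node
    # noise; otherwise fall back to a dense Cholesky of Sigma
    evR <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(evR) > 1e-10) {
      Z <- matrix(stats::rnorm(Tn * N), Tn, N)
      G <- matrix(stats::rnorm(Tn * length(tg$within)), Tn, length(tg$within))
      X <- sweep(Z, 2L, sqrt(1 - tg$within[memb]), "*") +
        (G %*% chol(R))[, memb, drop = FALSE]
    } else {
      Sigma <- R[memb, memb]
      diag(Sigma) <- 1
      X <- matrix(stats::rnorm(Tn * N), Tn, N) %*% chol(Sigma)
    }
    colnames(X) <- sprintf("ROI%03d", seq_len(N))
    attr(X, "subject_id") <- sprintf("S%03d", subjectIndex)
    attr(X, "targets") <- tg
    X
  })
}

#' Simulate a full cohort of time-series matrices
#'
#' @inheritParams simulateTimeSeries
#' @return named list of T x N matrices (`S001`, `S002`, ...).
#' @export
simulateCohort <- function(spec) {
  out <- lapply(seq_len(spec@nSubjects), function(i) simulateTimeSeries(spec, i))
  names(out) <- sprintf("S%03d", seq_len(spec@nSubjects))
  out
}

#' Simulate the behavioral table with a planted mediation structure
#'
#' Generates standardized latent variables with the planted standardized
#' paths `(a, b, cPrime)` of the spec and maps them onto instrument scales.
#' When `mValues` is supplied (a realized mediator, e.g. the subjects'
#' within-network VAN connectivity or a dot-probe bias score), the exposure
#' X is generated as `a * z(M) + sqrt(1 - a^2) * noise`, which plants a
#' population correlation of `a` between X and the realized mediator; the
#' realized path is reported in the `"paths"` attribute. When `mValues` is
#' `NULL` the mediator is generated internally as `M = a X + sqrt(1 - a^2) *
#' noise` (a behavioral mediator). The outcome is `Y = cPrime X + b z(M) +
#' ageY z(age) + sexY (sex - p) + disturbance`; with `noiseSd = NA` the
#' disturbance is scaled so Y has unit population variance.
#'
#' Instrument scales follow the cohort description of the source population:
#' ELS 37.35 +/- 8.34, depression 7.05 +/- 6.45, current stress 46.70 +/-
#' 20.88, age Normal(19.42, 1.40) truncated to 16-26 years, sex
#' Bernoulli(157/528). Simulated scores are Gaussian and may fall slightly
#' outside the hard instrument bounds of real questionnaires.
#'
#' @param spec a [CohortSpec-class].
#' @param mValues optional numeric vector of length `nSubjects`: the realized
#'   mediator.
#' @return `data.frame` with columns `subject_id, els, depression,
#'   current_stress, age, sex`, plus attributes `paths` (planted/realized
#'   standardized paths) and `latent` (the standardized X, M, Y draws).
#' @export
simulateBehavior <- function(spec, mValues = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n <- spec@nSubjects
  if (!is.null(mValues) && length(mValues) != n)
    .stopf("mValues must have length nSubjects = %d", n)
  co <- spec@mediationCoeffs
  a <- co[["a"]]; b <- co[["b"]]; cp <- co[["cPrime"]]
  g <- spec@nuisanceLoadings
  withSeed(childSeed(spec@seed, 2000L), {
    if (is.null(mValues)) {
      x <- stats::rnorm(n)
      m <- a * x + sqrt(1 - a^2) * stats::rnorm(n)
    } else {
      m <- zscore(mValues)
      x <- a * m + sqrt(1 - a^2) * stats::rnorm(n)
    }
    pMale <- 157 / 528
    sex <- stats::rbinom(n, 1L, pMale)
    age <- stats::rnorm(n, 19.42, 1.40)
    age <- pmin(pmax(age, 16), 26)
    ageZ <- (age - 19.42) / 1.40
    sexC <- sex - pMale
    explained <- cp^2 + b^2 + 2 * a * b * cp +
      g[["ageY"]]^2 + g[["sexY"]]^2 * pMale * (1 - pMale)
    if (is.na(spec@noiseSd)) {
      if (explained >= 1)
        .stopf("planted coefficients imply outcome variance >= 1 (R^2 = %.3f)", explained)
      sdY <- sqrt(1 - explained)
    } else sdY <- spec@noiseSd
    y <- cp * x + b * m + g[["ageY"]] * ageZ + g[["sexY"]] * sexC +
      stats::rnorm(n, 0, sdY)
    sX <- g[["stressX"]]
    stress <- sX * x + sqrt(1 - sX^2) * stats::rnorm(n)
    out <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      els = 37.35 + 8.34 * x,
      depression = 7.05 + 6.45 * y,
      current_stress = 46.70 + 20.88 * stress,
      age = age,
      sex = sex,
      stringsAsFactors = FALSE)
    attr(out, "paths") <- c(a = if (is.null(mValues)) a else stats::cor(x, m),
                            b = b, cPrime = cp)
    attr(out, "latent") <- data.frame(x = x, m = m, y = y)
    out
  })
}

#' Construct a DotProbeSpec
#'
#' Default trial counts per block follow the task design: NH 40, NS 37,
#' NA 37, NF 37 in each of 2 blocks of 151 trials (302 trials per subject).
#'
#' @param nSubjects number of subjects.
#' @param trialsPerCondition named integer vector of trials per condition
#'   per block.
#' @param nBlocks number of blocks.
#' @param baseRtMs mean congruent-trial RT in ms.
#' @param biasShiftMs named numeric: per-condition incongruent-minus-congruent
#'   RT shift in ms.
#' @param biasSdMs between-subject SD of the shift in ms.
#' @param rtNoiseSdMs trial-level Gaussian RT noise SD in ms.
#' @param errorRate probability of an incorrect response.
#' @param seed integer.
#' @return a validated [DotProbeSpec-class].
#' @export
dotProbeSpec <- function(nSubjects = 100L,
                         trialsPerCondition = c(NH = 40L, NS = 37L, "NA" = 37L, NF = 37L),
                         nBlocks = 2L, baseRtMs = 500, biasShiftMs = 0,
                         biasSdMs = 10, rtNoiseSdMs = 60, errorRate = 0.05,
                         seed = 1L) {
  conds <- names(trialsPerCondition)
  if (length(biasShiftMs) == 1L)
    biasShiftMs <- stats::setNames(rep(biasShiftMs, length(conds)), conds)
  new("DotProbeSpec",
      nSubjects = as.integer(nSubjects),
      trialsPerCondition = stats::setNames(as.integer(trialsPerCondition), conds),
      nBlocks = as.integer(nBlocks), baseRtMs = as.numeric(baseRtMs),
      biasShiftMs = biasShiftMs[conds], biasSdMs = as.numeric(biasSdMs),
      rtNoiseSdMs = as.numeric(rtNoiseSdMs), errorRate = as.numeric(errorRate),
      seed = as.integer(seed))
}

#' Simulate trial-level dot-probe logs
#'
#' For each subject, block and condition, emits trials with the emotional
#' face and probe sides balanced across the four (face, probe) cells. RT is
#' `baseRtMs + shift * incongruent + Gaussian noise`, where the subject's
#' shift per condition is drawn `Normal(biasShiftMs, biasSdMs)` and
#' incongruent means the probe appears opposite the emotional face; a
#' positive shift therefore yields a positive attention-bias score (toward
#' the emotional face). Nonpositive RT draws are resampled and counted in
#' the `"nResampled"` attribute. Errors are flagged at `errorRate`.
#'
#' @param spec a [DotProbeSpec-class].
#' @return `data.frame` with columns `subject_id, block, condition,
#'   face_side, probe_side, rt_ms, correct`, plus attributes
#'   `plantedShifts` (subject x condition matrix of realized shifts) and
#'   `nResampled`.
#' @export
simulateDotProbe <- function(spec) {
  stopifnot(is(spec, "DotProbeSpec"))
  validObject(spec)
  conds <- names(spec@trialsPerCondition)
  cells <- data.frame(face_side = c("L", "L", "R", "R"),
                      probe_side = c("L", "R", "L", "R"),
                      stringsAsFactors = FALSE)
  rows <- vector("list", spec@nSubjects)
  shifts <- matrix(NA_real_, spec@nSubjects, length(conds),
                   dimnames = list(sprintf("S%03d", seq_len(spec@nSubjects)), conds))
  nResampled <- 0L
  for (s in seq_len(spec@nSubjects)) {
    withSeed(childSeed(spec@seed, 3000L + s), {
      shifts[s, ] <- stats::rnorm(length(conds), spec@biasShiftMs, spec@biasSdMs)
      sub <- vector("list", spec@nBlocks * length(conds))
      k <- 0L
      for (blk in seq_len(spec@nBlocks)) {
        for (ci in seq_along(conds)) {
          nt <- spec@trialsPerCondition[ci]
          cell <- cells[sample(rep_len(1:4, nt)), , drop = FALSE]
          incong <- cell$face_side != cell$probe_side
          rt <- spec@baseRtMs + shifts[s, ci] * incong +
            stats::rnorm(nt, 0, spec@rtNoiseSdMs)
          bad <- which(rt <= 0)
          while (length(bad)) {
            nResampled <- nResampled + length(bad)
            rt[bad] <- spec@baseRtMs + shifts[s, ci] * incong[bad] +
              stats::rnorm(length(bad), 0, spec@rtNoiseSdMs)
            bad <- which(rt <= 0)
          }
          k <- k + 1L
          sub[[k]] <- data.frame(
            subject_id = sprintf("S%03d", s), block = blk,
            condition = conds[ci], face_side = cell$face_side,
            probe_side = cell$probe_side, rt_ms = rt,
            correct = stats::runif(nt) >= spec@errorRate,
            stringsAsFactors = FALSE)
        }
      }
      rows[[s]] <- do.call(rbind, sub)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "plantedShifts") <- shifts
  attr(out, "nResampled") <- nResampled
  out
}
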
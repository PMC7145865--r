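## Simple mediation (X -> M -> Y) by OLS with standardized coefficients and
## a bias-corrected bootstrap confidence interval for the indirect effect.

#' Standardized OLS path coefficients of a simple mediation model
#'
#' Fits the three regressions of the simple mediation model with identical
#' covariate sets: `m ~ x + covariates` (path a), `y ~ x + m + covariates`
#' (paths c' and b), and `y ~ x + covariates` (total effect c). With
#' `standardize = TRUE` (the default) x, m and y are z-scored before
#' fitting, so the returned paths are standardized regression coefficients;
#' covariates are left on their raw scale (this cannot change the focal
#' standardized paths). The OLS identity `c = cPrime + a * b` holds exactly.
#'
#' @param x,m,y numeric vectors of equal length n (`n > k + 4`).
#' @param covariates optional numeric matrix of k covariates.
#' @param standardize z-score x, m and y before fitting (default `TRUE`).
#' @return named numeric `c(a, b, c, cPrime)`.
#' @export
fitPaths <- function(x, m, y, covariates = NULL, standardize = TRUE) {
  n <- length(x)
  if (length(m) != n || length(y) != n) .stopf("x, m, y must have equal length")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) .stopf("covariates must have %d rows", n)
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + 4L) .stopf("need n > k + 4 (n = %d, k = %d)", n, k)
  if (standardize) { x <- zscore(x); m <- zscore(m); y <- zscore(y) }
  Zm <- cbind(1, x, covariates)
  Zy <- cbind(1, x, m, covariates)
  if (qr(Zy)$rank < ncol(Zy) || kappa(Zy, exact = FALSE) > 1e8)
    .stopf("collinear design: x, m and covariates are (nearly) linearly dependent")
  a <- stats::lm.fit(Zm, m)$coefficients[2L]
  fy <- stats::lm.fit(Zy, y)$coefficients
  cPrime <- fy[2L]; b <- fy[3L]
  cc <- stats::lm.fit(Zm, y)$coefficients[2L]
  out <- c(a = unname(a), b = unname(b), c = unname(cc), cPrime = unname(cPrime))
  if (anyNA(out)) .stopf("path coefficients undefined (degenerate design)")
  out
}

# vectorized no-covariate bootstrap of a*b over B resamples: standardized
# paths reduce to closed-form functions of the resample correlations
.bootAbPlain <- function(x, m, y, B, chunk = 500L) {
  n <- length(x)
  ab <- numeric(B)
  redraws <- 0L
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    idx <- matrix(sample.int(n, n * nb, replace = TRUE), n, nb)
    for (pass in 1:100) {
      Xb <- matrix(x[idx], n, nb); Mb <- matrix(m[idx], n, nb)
      Yb <- matrix(y[idx], n, nb)
      mx <- colMeans(Xb); mm <- colMeans(Mb); my <- colMeans(Yb)
      vx <- colMeans(Xb^2) - mx^2
      vm <- colMeans(Mb^2) - mm^2
      vy <- colMeans(Yb^2) - my^2
      rxm <- (colMeans(Xb * Mb) - mx * mm) / sqrt(vx * vm)
      rxy <- (colMeans(Xb * Yb) - mx * my) / sqrt(vx * vy)
      rmy <- (colMeans(Mb * Yb) - mm * my) / sqrt(vm * vy)
      bad <- which(!is.finite(rxm) | !is.finite(rxy) | !is.finite(rmy) |
                     abs(rxm) >= 1)
      if (!length(bad)) break
      redraws <- redraws + length(bad)
      if (pass == 100L)
        .stopf("too many degenerate bootstrap resamples (%d redraws)", redraws)
      idx[, bad] <- matrix(sample.int(n, n * length(bad), replace = TRUE),
                           n, length(bad))
    }
    aS <- rxm
    bS <- (rmy - rxm * rxy) / (1 - rxm^2)
    ab[done + seq_len(nb)] <- aS * bS
    done <- done + nb
  }
  list(ab = ab, redraws = redraws)
}

# general bootstrap with covariates: per-resample standardized OLS fits
.bootAbCov <- function(x, m, y, covariates, B) {
  n <- length(x)
  ab <- numeric(B)
  redraws <- 0L
  for (i in seq_len(B)) {
    for (pass in 1:100) {
      id <- sample.int(n, n, replace = TRUE)
      ok <- stats::sd(x[id]) > 0 && stats::sd(m[id]) > 0 && stats::sd(y[id]) > 0
      if (ok) {
        xi <- zscore(x[id]); mi <- zscore(m[id]); yi <- zscore(y[id])
        Zy <- cbind(1, xi, mi, covariates[id, , drop = FALSE])
        fy <- .lm.fit(Zy, yi)$coefficients
        ai <- .lm.fit(Zy[, -3L, drop = FALSE], mi)$coefficients[2L]
        val <- ai * fy[3L]
        if (is.finite(val)) { ab[i] <- val; break }
      }
      redraws <- redraws + 1L
      if (pass == 100L)
        .stopf("too many degenerate bootstrap resamples (%d redraws)", redraws)
    }
  }
  list(ab = ab, redraws = redraws)
}

#' Bootstrap confidence interval for the indirect effect
#'
#' Case-resampling bootstrap of the standardized indirect effect a*b.
#' Subjects are resampled with replacement `nBoot` times and the paths
#' refitted on each resample. The percentile interval takes the empirical
#' `alpha/2` and `1 - alpha/2` quantiles. The bias-corrected (BC) interval
#' computes \eqn{z_0 = \Phi^{-1}(\textrm{proportion of bootstrap estimates
#' below the point estimate})} (ties contribute a half count) and reads the
#' quantiles at \eqn{\Phi(2 z_0 \pm z_{1-\alpha/2})}. The effect is flagged
#' significant when the interval excludes zero. No acceleration term is
#' used (BC, not BCa).
#'
#' Degenerate resamples (a constant x, m or y) are redrawn and counted; a
#' bootstrap distribution lying entirely on one side of the point estimate
#' is flagged pathological (the bias correction is then clamped).
#'
#' @inheritParams fitPaths
#' @param nBoot number of bootstrap resamples (default 2000, minimum 200).
#' @param ciLevel confidence level (default 0.95).
#' @param method `"bias_corrected"` (default) or `"percentile"`.
#' @param seed integer.
#' @return a [MediationResult-class].
#' @examples
#' set.seed(7)
#' x <- rnorm(150); m <- 0.5 * x + rnorm(150); y <- 0.4 * m + rnorm(150)
#' bootstrapIndirect(x, m, y, nBoot = 500, seed = 1)
#' @export
bootstrapIndirect <- function(x, m, y, covariates = NULL, nBoot = 2000,
                              ciLevel = 0.95, method = c("bias_corrected", "percentile"),
                              seed = 1L) {
  method <- match.arg(method)
  nBoot <- as.integer(nBoot)
  if (nBoot < 200L) .stopf("nBoot must be at least 200 for CI estimation")
  if (ciLevel <= 0 || ciLevel >= 1) .stopf("ciLevel must lie in (0, 1)")
  paths <- fitPaths(x, m, y, covariates, standardize = TRUE)
  point <- paths[["a"]] * paths[["b"]]
  boot <- withSeed(childSeed(seed, 4242L), {
    if (is.null(covariates)) {
      .bootAbPlain(x, m, y, nBoot)
    } else {
      .bootAbCov(x, m, y, as.matrix(covariates), nBoot)
    }
  })
  ab <- boot$ab
  alpha <- 1 - ciLevel
  zc <- stats::qnorm(1 - alpha / 2)
  pathological <- FALSE
  if (method == "percentile") {
    z0 <- 0
    probs <- c(alpha / 2, 1 - alpha / 2)
  } else {
    propBelow <- (sum(ab < point) + 0.5 * sum(ab == point)) / nBoot
    if (propBelow <= 0 || propBelow >= 1) {
      pathological <- TRUE
      propBelow <- min(max(propBelow, 1 / (2 * nBoot)), 1 - 1 / (2 * nBoot))
    }
    z0 <- stats::qnorm(propBelow)
    probs <- stats::pnorm(2 * z0 + c(-zc, zc))
  }
  ci <- unname(stats::quantile(ab, probs, names = FALSE, type = 7))
  if (method == "bias_corrected" && (point < ci[1] || point > ci[2]))
    pathological <- TRUE
  new("MediationResult",
      paths = paths, indirect = point, ciLow = ci[1], ciHigh = ci[2],
      nBoot = nBoot, ciLevel = ciLevel, method = method,
      significant = (ci[1] > 0 || ci[2] < 0), z0 = z0,
      nRedraws = as.integer(boot$redraws), pathological = pathological,
      bootEstimates = ab, seed = as.integer(seed))
}

#' Fit the two study mediation models
#'
#' Model 1 ("van"): X = ELS, M = within-network connectivity of the VAN,
#' Y = depression. Model 2 ("sad_bias", fitted when bias scores are
#' supplied): X = ELS, M = attention bias to the sad face (NS condition),
#' Y = depression. Both adjust for age and sex by default.
#'
#' @param object a [ConnectivityExperiment-class] with behavioral `colData`
#'   (columns `els`, `depression`, and the covariates).
#' @param biasScores optional tidy bias-score table from [scoreCohort()];
#'   subjects with a missing sad-face score are dropped from model 2 with a
#'   warning.
#' @param covariates character vector of covariate column names (default
#'   `covariatePreset("age_sex")`).
#' @param mediatorMeasure row name of the connectivity mediator (default
#'   `"within_VAN"`).
#' @inheritParams bootstrapIndirect
#' @return named list of [MediationResult-class] objects (`van`, and
#'   `sad_bias` when bias scores are supplied).
#' @export
runMediationModels <- function(object, biasScores = NULL,
                               covariates = covariatePreset("age_sex"),
                               mediatorMeasure = "within_VAN",
                               nBoot = 2000, ciLevel = 0.95,
                               method = "bias_corrected", seed = 1L) {
  stopifnot(is(object, "ConnectivityExperiment"))
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  need <- c("els", "depression", covariates)
  if (!all(need %in% colnames(cd)))
    .stopf("behavioral variable(s) not found: %s",
           paste(setdiff(need, colnames(cd)), collapse = ", "))
  if (!mediatorMeasure %in% rownames(object))
    .stopf("mediator measure '%s' not found in the connectivity profiles",
           mediatorMeasure)
  covs <- if (length(covariates)) as.matrix(cd[, covariates, drop = FALSE]) else NULL
  mVan <- connectivityValues(object)[mediatorMeasure, ]
  out <- list(van = bootstrapIndirect(cd$els, mVan, cd$depression, covs,
                                      nBoot = nBoot, ciLevel = ciLevel,
                                      method = method, seed = childSeed(seed, 1L)))
  if (!is.null(biasScores)) {
    ns <- biasScores[biasScores$emotion == "NS", , drop = FALSE]
    idx <- match(colnames(object), ns$subject_id)
    bias <- ns$bias_ms[idx]
    keep <- !is.na(bias)
    if (!any(keep)) .stopf("no subjects with a sad-face bias score")
    if (any(!keep))
      .warnf("dropping %d subject(s) without a sad-face bias score", sum(!keep))
    out$sad_bias <- bootstrapIndirect(cd$els[keep], bias[keep],
                                      cd$depression[keep],
                                      if (is.null(covs)) NULL else covs[keep, , drop = FALSE],
                                      nBoot = nBoot, ciLevel = ciLevel,
                                      method = method, seed = childSeed(seed, 2L))
  }
  out
}
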
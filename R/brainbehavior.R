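## Covariate-adjusted correlation screening of connectivity measures against
## a behavioral score, with Benjamini-Hochberg FDR control.

#' Partial correlation with covariate adjustment
#'
#' The partial correlation of `x` and `y` given a covariate matrix: the
#' Pearson correlation of the residuals of `x` and `y` after OLS on
#' `[intercept, covariates]`. Computed here through the inverse covariance
#' matrix of `(x, y, covariates)` (numerically equivalent to explicit
#' residualization). The two-sided p-value comes from
#' \eqn{t = r \sqrt{df / (1 - r^2)}} with \eqn{df = n - 2 - k}.
#'
#' @param x,y numeric vectors of equal length n.
#' @param covariates numeric matrix (or vector, or `NULL`) of k covariates;
#'   must be full rank and satisfy `n > k + 3`.
#' @return list with elements `r`, `p`, `df`.
#' @examples
#' x <- rnorm(50); z <- rnorm(50); y <- 0.5 * z + rnorm(50)
#' partialCorrelation(x, y, z)
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) .stopf("x and y must have equal length")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) .stopf("covariates must have %d rows", n)
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + 3L) .stopf("need n > k + 3 (n = %d, k = %d)", n, k)
  if (k == 0L) {
    r <- stats::cor(x, y)
  } else {
    if (qr(cbind(1, covariates))$rank < k + 1L)
      .stopf("covariate matrix is rank deficient")
    S <- stats::cov(cbind(x, y, covariates))
    Om <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Om) || !all(is.finite(Om)))
      .stopf("degenerate problem: x or y is collinear with the covariates")
    r <- -Om[1L, 2L] / sqrt(Om[1L, 1L] * Om[2L, 2L])
  }
  if (!is.finite(r))
    .stopf("degenerate problem: partial correlation undefined (constant residual)")
  df <- n - 2L - k
  r <- min(max(r, -1), 1)
  p <- if (abs(r) == 1) 0 else 2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  list(r = r, p = p, df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR control: adjusted \eqn{p_{(i)} = \min_{j \ge i} \min(1, m
#' p_{(j)} / j)}; hypotheses with adjusted p at or below `q` are rejected.
#' Ties are handled stably in input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param q target false-discovery rate in `(0, 1)`.
#' @return list with `adjusted` (numeric) and `reject` (logical), both in
#'   input order.
#' @export
bhFdr <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    .stopf("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) .stopf("q must lie in (0, 1)")
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Covariate presets for the behavioral analyses
#'
#' Two covariate sets are used in the analyses this package implements: the
#' connectivity screen adjusts for age and sex, while the
#' behavior-to-behavior correlations additionally adjust for current
#' stress.
#'
#' @param preset `"age_sex"` or `"age_sex_stress"`.
#' @return character vector of behavioral column names.
#' @export
covariatePreset <- function(preset = c("age_sex", "age_sex_stress")) {
  switch(match.arg(preset),
         age_sex = c("age", "sex"),
         age_sex_stress = c("age", "sex", "current_stress"))
}

#' Screen connectivity measures against a behavioral score
#'
#' For every connectivity measure (10 within-network + 45 between-network
#' values by default) computes the covariate-adjusted partial correlation
#' with the target score and applies Benjamini-Hochberg FDR correction
#' jointly across all tests in the screen (within and between measures form
#' one family; use `measures` to restrict the family).
#'
#' @param object a [ConnectivityExperiment-class] whose `colData` carries
#'   the behavioral variables, or whose behavior is supplied via `behavior`.
#' @param target name of the behavioral score to screen against
#'   (default `"els"`).
#' @param covariates character vector of behavioral covariate names
#'   (default `covariatePreset("age_sex")`); `character(0)` for unadjusted
#'   correlations.
#' @param q false-discovery rate (default 0.05).
#' @param measures optional character vector restricting the screen (and the
#'   FDR family) to a subset of row names.
#' @param behavior optional behavioral `data.frame` with `subject_id`
#'   overriding `colData`; subjects must match the experiment's columns.
#' @return `data.frame` with columns `measure, measure_type,
#'   network_or_pair, r, p, p_adj, significant`.
#' @export
screenConnectivity <- function(object, target = "els",
                               covariates = covariatePreset("age_sex"),
                               q = 0.05, measures = NULL, behavior = NULL) {
  stopifnot(is(object, "ConnectivityExperiment"))
  cd <- if (is.null(behavior)) {
    as.data.frame(SummarizedExperiment::colData(object))
  } else {
    if (!"subject_id" %in% colnames(behavior))
      .stopf("behavior table must contain a subject_id column")
    unmatched <- setdiff(colnames(object), behavior$subject_id)
    if (length(unmatched))
      .stopf("subjects missing from behavior table: %s",
             paste(unmatched, collapse = ", "))
    behavior[match(colnames(object), behavior$subject_id), , drop = FALSE]
  }
  need <- c(target, covariates)
  if (!all(need %in% colnames(cd)))
    .stopf("behavioral variable(s) not found: %s",
           paste(setdiff(need, colnames(cd)), collapse = ", "))
  X <- t(connectivityValues(object))
  if (!is.null(measures)) {
    miss <- setdiff(measures, colnames(X))
    if (length(miss)) .stopf("unknown measure(s): %s", paste(miss, collapse = ", "))
    X <- X[, measures, drop = FALSE]
  }
  y <- cd[[target]]
  n <- nrow(X)
  k <- length(covariates)
  if (n <= k + 3L) .stopf("need n > k + 3 (n = %d, k = %d)", n, k)
  # residualize the target and every measure on [1, covariates] in one QR
  Z <- cbind(`(Intercept)` = rep(1, n))
  if (k) Z <- cbind(Z, as.matrix(cd[, covariates, drop = FALSE]))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) .stopf("covariate matrix is rank deficient")
  ry <- qr.resid(qz, y)
  rx <- qr.resid(qz, X)
  num <- colSums(rx * ry)
  den <- sqrt(colSums(rx^2) * sum(ry^2))
  r <- pmin(pmax(num / den, -1), 1)
  df <- n - 2L - k
  p <- ifelse(abs(r) == 1, 0, 2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df))
  fdr <- bhFdr(p, q)
  rd <- SummarizedExperiment::rowData(object)[colnames(X), , drop = FALSE]
  data.frame(
    measure = colnames(X),
    measure_type = as.character(rd$measure_type),
    network_or_pair = ifelse(rd$measure_type == "within",
                             as.character(rd$network_a),
                             paste(rd$network_a, rd$network_b, sep = "-")),
    r = unname(r), p = unname(p), p_adj = fdr$adjusted,
    significant = fdr$reject,
    row.names = NULL, stringsAsFactors = FALSE)
}
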
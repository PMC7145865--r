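## Cross-validated linear support vector regression predicting a behavioral
## score from connectivity features, with balanced folds and a permutation
## test for r(predicted, observed).

#' Outcome-balanced cross-validation folds
#'
#' Subjects are sorted by the outcome, taken in consecutive groups of k, and
#' each group is dealt round-robin into the k folds (order within a group
#' randomized by the seed). Fold sizes differ by at most one and every fold
#' receives subjects from the full range of the outcome, keeping the
#' per-fold outcome distributions balanced.
#'
#' @param y numeric outcome vector (length n, `n >= 2k`).
#' @param k fold count.
#' @param seed integer.
#' @return a [FoldAssignment-class].
#' @examples
#' foldOf(balancedFolds(1:8, k = 4, seed = 1))
#' @export
balancedFolds <- function(y, k, seed) {
  n <- length(y)
  k <- as.integer(k)
  if (k < 2L) .stopf("k must be at least 2")
  if (n < 2L * k) .stopf("need at least 2k subjects (n = %d, k = %d)", n, k)
  ord <- order(y)
  fold <- integer(n)
  withSeed(childSeed(seed, 577L), {
    start <- 1L
    while (start <= n) {
      grp <- ord[start:min(start + k - 1L, n)]
      fold[grp] <- sample(k)[seq_along(grp)]
      start <- start + k
    }
  })
  if (!is.null(names(y))) names(fold) <- names(y)
  new("FoldAssignment", fold = fold, k = k)
}

# training-fold standardization; constant features get unit scale
.standardize <- function(train, test) {
  mu <- colMeans(train)
  sds <- apply(train, 2L, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sds, "/"),
       test = sweep(sweep(test, 2L, mu), 2L, sds, "/"))
}

#' Cross-validated linear SVR prediction
#'
#' Trains an epsilon-insensitive linear support vector regression on each
#' set of k-1 training folds and predicts the held-out fold, so that every
#' subject is predicted exactly once by a model never trained on it.
#' Features are standardized with training-fold statistics only. When
#' covariates are supplied, the outcome is replaced by its residual from an
#' OLS fit on the covariates estimated on the training folds only (the
#' held-out residuals use the training-fold coefficients), so no held-out
#' information leaks into training. The summary statistic is the Pearson
#' correlation between the pooled out-of-fold predictions and the observed
#' targets.
#'
#' @param features numeric subject x measure matrix (or a
#'   [ConnectivityExperiment-class], whose assay is transposed internally).
#' @param y numeric outcome, or the name of a `colData` column when
#'   `features` is a `ConnectivityExperiment`.
#' @param covariates optional numeric matrix of nuisance covariates (or
#'   character vector of `colData` columns).
#' @param k fold count (default 4).
#' @param C SVR cost parameter (default 1).
#' @param epsilon SVR insensitivity (default 0.1).
#' @param seed integer; fixes the fold assignment.
#' @param residualizeFeatures also residualize the features on the
#'   covariates (training-fold fits); default `FALSE`.
#' @param costGrid optional numeric vector of costs; when given, C is chosen
#'   per training set by inner cross-validation (off by default, mirroring a
#'   fixed-model design).
#' @return a [PredictionResult-class].
#' @export
cvPredict <- function(features, y, covariates = NULL, k = 4, C = 1,
                      epsilon = 0.1, seed = 1L, residualizeFeatures = FALSE,
                      costGrid = NULL) {
  if (is(features, "ConnectivityExperiment")) {
    ce <- features
    cd <- as.data.frame(SummarizedExperiment::colData(ce))
    if (is.character(y) && length(y) == 1L) y <- cd[[y]]
    if (is.character(covariates))
      covariates <- as.matrix(cd[, covariates, drop = FALSE])
    features <- t(connectivityValues(ce))
  }
  features <- as.matrix(features)
  n <- nrow(features)
  if (ncol(features) < 1L) .stopf("at least one feature is required")
  if (length(y) != n) .stopf("y must have length %d", n)
  if (stats::sd(y) == 0) .stopf("outcome is constant")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) .stopf("covariates must have %d rows", n)
  }
  folds <- balancedFolds(y, k, seed)
  fold <- foldOf(folds)
  pred <- obs <- numeric(n)
  for (f in seq_len(folds@k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    ytr <- y[tr]; yte <- y[te]
    Xtr <- features[tr, , drop = FALSE]
    Xte <- features[te, , drop = FALSE]
    if (!is.null(covariates)) {
      fit <- stats::lm.fit(cbind(1, covariates[tr, , drop = FALSE]), ytr)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      ytr <- ytr - cbind(1, covariates[tr, , drop = FALSE]) %*% beta
      yte <- yte - cbind(1, covariates[te, , drop = FALSE]) %*% beta
      ytr <- drop(ytr); yte <- drop(yte)
      if (residualizeFeatures) {
        qz <- qr(cbind(1, covariates[tr, , drop = FALSE]))
        gamma <- qr.coef(qz, Xtr)
        gamma[is.na(gamma)] <- 0
        Xtr <- Xtr - cbind(1, covariates[tr, , drop = FALSE]) %*% gamma
        Xte <- Xte - cbind(1, covariates[te, , drop = FALSE]) %*% gamma
      }
    }
    st <- .standardize(Xtr, Xte)
    Cf <- C
    if (!is.null(costGrid)) {
      tuned <- e1071::tune(e1071::svm, train.x = st$train, train.y = ytr,
                           kernel = "linear", scale = FALSE, epsilon = epsilon,
                           ranges = list(cost = costGrid))
      Cf <- tuned$best.parameters$cost
    }
    model <- e1071::svm(st$train, ytr, type = "eps-regression",
                        kernel = "linear", cost = Cf, epsilon = epsilon,
                        scale = FALSE)
    pred[te] <- stats::predict(model, st$test)
    obs[te] <- yte
  }
  new("PredictionResult",
      rPredObs = stats::cor(pred, obs), predictions = pred, observed = obs,
      folds = folds, cost = C, epsilon = epsilon, seed = as.integer(seed))
}

#' Permutation p-value for the cross-validated prediction accuracy
#'
#' Permutes the outcome against the features and reruns the full
#' cross-validated prediction for each permutation; the p-value is
#' \eqn{(1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}.
#'
#' @inheritParams cvPredict
#' @param nPerm number of permutations (at least 100).
#' @return list with elements `p`, `rObserved`, `rPermuted`.
#' @export
permutationPvalue <- function(features, y, covariates = NULL, k = 4, C = 1,
                              epsilon = 0.1, nPerm = 200, seed = 1L) {
  if (nPerm < 100) .stopf("nPerm must be at least 100")
  if (is(features, "ConnectivityExperiment")) {
    ce <- features
    cd <- as.data.frame(SummarizedExperiment::colData(ce))
    if (is.character(y) && length(y) == 1L) y <- cd[[y]]
    if (is.character(covariates))
      covariates <- as.matrix(cd[, covariates, drop = FALSE])
    features <- t(connectivityValues(ce))
  }
  rObs <- rPredObs(cvPredict(features, y, covariates, k, C, epsilon, seed))
  n <- length(y)
  rPerm <- withSeed(childSeed(seed, 811L), {
    vapply(seq_len(nPerm), function(i) {
      yp <- y[sample.int(n)]
      rPredObs(cvPredict(features, yp, covariates, k, C, epsilon,
                         childSeed(seed, 811L + i)))
    }, numeric(1))
  })
  list(p = (1 + sum(rPerm >= rObs)) / (1 + nPerm),
       rObserved = rObs, rPermuted = rPerm)
}
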
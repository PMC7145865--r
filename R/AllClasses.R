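#' @import methods
#' @importFrom stats cor sd quantile qnorm pnorm pt rnorm runif rbinom
#' @importFrom utils read.csv write.csv read.delim write.table
NULL

## ------------------------------------------------------------------------
## NetworkPartition
## ------------------------------------------------------------------------

#' Assignment of ROI nodes to named brain networks
#'
#' A `NetworkPartition` maps each node (ROI) to exactly one named network and
#' fixes an ordering of the networks. It defines the blocks over which the
#' within-network statistic \eqn{W_a} and the between-network statistic
#' \eqn{PB_{a-b}} are averaged.
#'
#' @slot nodeIds character vector of unique node identifiers.
#' @slot networks factor of the same length as `nodeIds`; levels are the
#'   network names in their canonical order and every level must be nonempty.
#'
#' @seealso [NetworkPartition()], [withinNetworkConnectivity()],
#'   [betweenNetworkConnectivity()]
#' @exportClass NetworkPartition
setClass("NetworkPartition",
  representation(nodeIds = "character", networks = "factor"))

setValidity("NetworkPartition", function(object) {
  msg <- character()
  if (length(object@nodeIds) != length(object@networks))
    msg <- c(msg, "nodeIds and networks must have equal length")
  if (anyDuplicated(object@nodeIds))
    msg <- c(msg, "node identifiers must be unique")
  if (anyNA(object@networks))
    msg <- c(msg, "every node must be assigned to a network")
  tab <- table(object@networks)
  if (any(tab == 0))
    msg <- c(msg, sprintf("empty network(s): %s",
                          paste(names(tab)[tab == 0], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a NetworkPartition
#'
#' @param nodeIds character vector of unique node (ROI) identifiers.
#' @param networks character or factor giving the network of each node. If a
#'   character vector, network order defaults to order of first appearance.
#' @param networkOrder optional character vector fixing the network ordering.
#' @return A [NetworkPartition-class] object.
#' @examples
#' p <- NetworkPartition(paste0("n", 1:5), c("VAN", "VAN", "DAN", "DAN", "DAN"))
#' networkSizes(p)
#' @export
NetworkPartition <- function(nodeIds, networks, networkOrder = NULL) {
  if (is.null(networkOrder))
    networkOrder <- if (is.factor(networks)) levels(networks) else unique(as.character(networks))
  new("NetworkPartition",
      nodeIds = as.character(nodeIds),
      networks = factor(as.character(networks), levels = networkOrder))
}

## ------------------------------------------------------------------------
## CohortSpec
## ------------------------------------------------------------------------

#' Specification of a synthetic resting-state cohort
#'
#' `CohortSpec` fixes the study conditions for the synthetic-data generator:
#' the cohort size, the length of each ROI time series, the node-to-network
#' partition sizes, the target within-/between-network correlations of the
#' block-structured (compound-symmetric within each network) covariance, the
#' planted standardized mediation paths, and the master seed. Validity checks
#' that the implied node-level correlation matrix is positive definite, using
#' the reduced eigenvalue test for block compound-symmetric matrices: the
#' spectrum is \eqn{\{1-\rho_a\}} plus the eigenvalues of the K x K matrix
#' with diagonal \eqn{1+(N_a-1)\rho_a} and off-diagonal
#' \eqn{\sqrt{N_a N_b}\,\rho_{ab}}.
#'
#' @slot nSubjects integer, number of subjects.
#' @slot tPoints integer, time points per subject.
#' @slot partitionSizes named integer vector of node counts per network.
#' @slot withinTargets named numeric in `[0, 1)`, per-network target
#'   within-block correlation.
#' @slot betweenTargets symmetric numeric matrix (networks x networks) of
#'   target between-block correlations in `(-1, 1)`; the diagonal is ignored.
#' @slot mediationCoeffs named numeric `c(a, b, cPrime)` of standardized
#'   planted paths for the X -> M -> Y structure.
#' @slot noiseSd numeric; SD of the outcome disturbance. `NA` (the default)
#'   auto-scales the disturbance so the outcome has unit variance and the
#'   planted paths are exactly the standardized coefficients.
#' @slot perturbSd numeric; SD of the per-subject perturbation of the
#'   connectivity targets (inter-subject variance of true connectivity).
#' @slot nuisanceLoadings named numeric `c(ageY, sexY, stressX)`: loadings of
#'   age and sex on the outcome and the correlation of current stress with X.
#' @slot seed integer master seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nSubjects = "integer", tPoints = "integer",
                 partitionSizes = "integer", withinTargets = "numeric",
                 betweenTargets = "matrix", mediationCoeffs = "numeric",
                 noiseSd = "numeric", perturbSd = "numeric",
                 nuisanceLoadings = "numeric", seed = "integer"))

# eigenvalues of the block compound-symmetric correlation matrix, computed
# from the K x K reduced matrix (exact; avoids forming the N x N matrix)
.blockEigen <- function(sizes, within, between) {
  K <- length(sizes)
  S <- sqrt(outer(sizes, sizes)) * between
  diag(S) <- 1 + (sizes - 1) * within
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  c(ev, rep(1 - within[sizes > 1], pmax(sizes[sizes > 1] - 1, 0)))
}

setValidity("CohortSpec", function(object) {
  msg <- character()
  K <- length(object@partitionSizes)
  nm <- names(object@partitionSizes)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "partitionSizes must have unique network names")
  if (any(object@partitionSizes < 1)) msg <- c(msg, "node counts must be positive")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be positive")
  if (object@tPoints < 3L) msg <- c(msg, "tPoints must be at least 3")
  if (!identical(names(object@withinTargets), nm))
    msg <- c(msg, "withinTargets must be named like partitionSizes")
  if (any(object@withinTargets < 0 | object@withinTargets >= 1))
    msg <- c(msg, "within-network targets must lie in [0, 1)")
  if (!identical(dim(object@betweenTargets), c(K, K)))
    msg <- c(msg, "betweenTargets must be a K x K matrix")
  else {
    off <- object@betweenTargets[upper.tri(object@betweenTargets)]
    if (any(abs(off) >= 1)) msg <- c(msg, "between-network targets must lie in (-1, 1)")
    if (max(abs(object@betweenTargets - t(object@betweenTargets))) > 1e-12)
      msg <- c(msg, "betweenTargets must be symmetric")
  }
  if (!identical(names(object@mediationCoeffs), c("a", "b", "cPrime")))
    msg <- c(msg, "mediationCoeffs must be named c(a, b, cPrime)")
  if (object@perturbSd < 0) msg <- c(msg, "perturbSd must be nonnegative")
  if (!length(msg)) {
    ev <- .blockEigen(object@partitionSizes, object@withinTargets,
                      object@betweenTargets)
    if (min(ev) <= 1e-10) {
      worst <- which.min(.blockEigen(object@partitionSizes,
                                     object@withinTargets,
                                     object@betweenTargets))
      msg <- c(msg, sprintf(
        "implied block covariance is not positive definite (min eigenvalue %.3e); check the within/between targets of networks %s",
        min(ev), paste(nm, collapse = ", ")))
    }
    co <- object@mediationCoeffs
    if (is.na(object@noiseSd)) {
      s2 <- 1 - (co["cPrime"]^2 + co["b"]^2 + 2 * prod(co))
      if (!is.na(s2) && s2 <= 0)
        msg <- c(msg, "mediation coefficients imply outcome R^2 >= 1; reduce a, b or cPrime")
    } else if (object@noiseSd <= 0)
      msg <- c(msg, "noiseSd must be positive (or NA for auto-scaling)")
  }
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------------
## DotProbeSpec
## ------------------------------------------------------------------------

#' Specification of a synthetic dot-probe experiment
#'
#' Conditions are the four emotion face pairs: NH (neutral-happy), NS
#' (neutral-sad), NA (neutral-anger), NF (neutral-fear). The default trial
#' counts per block are NH 40, NS 37, NA 37, NF 37, in 2 blocks of 151
#' trials (302 per subject).
#'
#' @slot nSubjects integer.
#' @slot trialsPerCondition named integer, trials per condition per block.
#' @slot nBlocks integer number of blocks.
#' @slot baseRtMs positive numeric, mean RT on congruent trials.
#' @slot biasShiftMs named numeric per condition: incongruent-minus-congruent
#'   RT shift in ms (positive = attention toward the emotional face).
#' @slot biasSdMs nonnegative numeric, between-subject SD of the shift.
#' @slot rtNoiseSdMs nonnegative numeric, trial-level Gaussian RT noise SD.
#' @slot errorRate numeric in `[0, 1)`, probability a trial is incorrect.
#' @slot seed integer.
#' @exportClass DotProbeSpec
setClass("DotProbeSpec",
  representation(nSubjects = "integer", trialsPerCondition = "integer",
                 nBlocks = "integer", baseRtMs = "numeric",
                 biasShiftMs = "numeric", biasSdMs = "numeric",
                 rtNoiseSdMs = "numeric", errorRate = "numeric",
                 seed = "integer"))

setValidity("DotProbeSpec", function(object) {
  msg <- character()
  conds <- names(object@trialsPerCondition)
  if (is.null(conds) || anyDuplicated(conds))
    msg <- c(msg, "trialsPerCondition must have unique condition names")
  if (any(object@trialsPerCondition < 1))
    msg <- c(msg, "trial counts must be positive")
  if (!identical(sort(names(object@biasShiftMs)), sort(conds)))
    msg <- c(msg, "biasShiftMs must be named by the same conditions")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be positive")
  if (object@nBlocks < 1L) msg <- c(msg, "nBlocks must be positive")
  if (object@baseRtMs <= 0) msg <- c(msg, "baseRtMs must be positive")
  if (object@rtNoiseSdMs < 0 || object@biasSdMs < 0)
    msg <- c(msg, "RT noise and bias SDs must be nonnegative")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------------
## ConnectivityExperiment
## ------------------------------------------------------------------------

#' Cohort container for network-connectivity profiles
#'
#' A `ConnectivityExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class]. The `"connectivity"`
#' assay holds one row per connectivity measure (10 within-network values and
#' 45 between-network values for a 10-network partition) and one column per
#' subject; `rowData` carries the measure type and network label(s); `colData`
#' carries the behavioral table (ELS, depression, current stress, age, sex).
#'
#' @seealso [profileCohort()], [screenConnectivity()], [cvPredict()],
#'   [runMediationModels()]
#' @exportClass ConnectivityExperiment
#' @import SummarizedExperiment
setClass("ConnectivityExperiment", contains = "SummarizedExperiment")

setValidity("ConnectivityExperiment", function(object) {
  msg <- character()
  if (!"connectivity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'connectivity' is required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("measure_type", "network_a", "network_b")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, sprintf("rowData must contain columns %s",
                          paste(need, collapse = ", ")))
  else if (!all(rd$measure_type %in% c("within", "between")))
    msg <- c(msg, "measure_type must be 'within' or 'between'")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------------
## FoldAssignment
## ------------------------------------------------------------------------

#' Balanced cross-validation fold assignment
#'
#' @slot fold integer vector of fold indices in `1:k`, one per subject
#'   (named when subject identifiers are available).
#' @slot k integer fold count.
#' @exportClass FoldAssignment
setClass("FoldAssignment", representation(fold = "integer", k = "integer"))

setValidity("FoldAssignment", function(object) {
  msg <- character()
  if (any(object@fold < 1L) || any(object@fold > object@k))
    msg <- c(msg, "fold indices must lie in 1:k")
  sizes <- tabulate(object@fold, nbins = object@k)
  if (diff(range(sizes)) > 1L)
    msg <- c(msg, "fold sizes must differ by at most 1")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------------
## PredictionResult
## ------------------------------------------------------------------------

#' Cross-validated prediction result
#'
#' Out-of-fold predictions from balanced-fold linear support vector
#' regression, and the Pearson correlation between pooled predictions and
#' the observed targets (`rPredObs`). Every subject is predicted exactly
#' once, by a model never trained on it.
#'
#' @slot rPredObs numeric scalar, \eqn{r_{predicted, observed}}.
#' @slot predictions numeric, out-of-fold predicted values (subject order).
#' @slot observed numeric, the targets the predictions are compared with
#'   (the outcome, or its training-fold covariate residual when covariates
#'   are supplied).
#' @slot folds a [FoldAssignment-class].
#' @slot cost,epsilon numeric SVR hyperparameters (cost C and insensitivity).
#' @slot seed integer.
#' @exportClass PredictionResult
setClass("PredictionResult",
  representation(rPredObs = "numeric", predictions = "numeric",
                 observed = "numeric", folds = "FoldAssignment",
                 cost = "numeric", epsilon = "numeric", seed = "integer"))

## ------------------------------------------------------------------------
## MediationResult
## ------------------------------------------------------------------------

#' Simple-mediation result with bootstrap confidence interval
#'
#' Standardized OLS path coefficients of the X -> M -> Y model (a: X to M;
#' b: M to Y given X; c: total; c': direct), the indirect effect a*b, and a
#' case-resampling bootstrap confidence interval (bias-corrected or
#' percentile). The OLS identity c = c' + a*b holds exactly when the same
#' covariates enter every equation.
#'
#' @slot paths named numeric `c(a, b, c, cPrime)`.
#' @slot indirect numeric, the a*b point estimate.
#' @slot ciLow,ciHigh numeric bootstrap CI bounds.
#' @slot nBoot integer number of bootstrap resamples.
#' @slot ciLevel numeric confidence level.
#' @slot method `"bias_corrected"` or `"percentile"`.
#' @slot significant logical: CI excludes zero.
#' @slot z0 numeric bias-correction constant (0 for percentile).
#' @slot nRedraws integer count of degenerate resamples that were redrawn.
#' @slot pathological logical: flagged when the bootstrap distribution is
#'   one-sided of the point estimate or the point estimate falls outside a
#'   bias-corrected interval.
#' @slot bootEstimates numeric vector of bootstrap indirect effects.
#' @slot seed integer.
#' @exportClass MediationResult
setClass("MediationResult",
  representation(paths = "numeric", indirect = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", nBoot = "integer",
                 ciLevel = "numeric", method = "character",
                 significant = "logical", z0 = "numeric",
                 nRedraws = "integer", pathological = "logical",
                 bootEstimates = "numeric", seed = "integer"))
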
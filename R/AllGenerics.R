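#' Accessors for elsnet classes
#'
#' @param object an elsnet S4 object.
#' @name elsnet-accessors
NULL

#' @rdname elsnet-accessors
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname elsnet-accessors
#' @export
setGeneric("networkNames", function(object) standardGeneric("networkNames"))

#' @rdname elsnet-accessors
#' @export
setGeneric("networkSizes", function(object) standardGeneric("networkSizes"))

#' @rdname elsnet-accessors
#' @export
setGeneric("networkOf", function(object, nodes) standardGeneric("networkOf"))

#' @rdname elsnet-accessors
#' @export
setGeneric("connectivityValues", function(object) standardGeneric("connectivityValues"))

#' @rdname elsnet-accessors
#' @export
setGeneric("measureType", function(object) standardGeneric("measureType"))

#' @rdname elsnet-accessors
#' @export
setGeneric("foldOf", function(object) standardGeneric("foldOf"))

#' @rdname elsnet-accessors
#' @export
setGeneric("rPredObs", function(object) standardGeneric("rPredObs"))

#' @rdname elsnet-accessors
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))

#' @rdname elsnet-accessors
#' @export
setGeneric("pathCoefficients", function(object) standardGeneric("pathCoefficients"))

#' @rdname elsnet-accessors
#' @export
setGeneric("indirectEffect", function(object) standardGeneric("indirectEffect"))

#' @rdname elsnet-accessors
#' @export
setGeneric("isSignificant", function(object) standardGeneric("isSignificant"))

## ---- NetworkPartition ----

#' @rdname elsnet-accessors
setMethod("nodeIds", "NetworkPartition", function(object) object@nodeIds)

#' @rdname elsnet-accessors
setMethod("networkNames", "NetworkPartition", function(object) levels(object@networks))

#' @rdname elsnet-accessors
setMethod("networkSizes", "NetworkPartition", function(object) {
  out <- table(object@networks)
  stats::setNames(as.integer(out), names(out))
})

#' @rdname elsnet-accessors
#' @param nodes node identifiers to look up.
setMethod("networkOf", "NetworkPartition", function(object, nodes) {
  idx <- match(nodes, object@nodeIds)
  if (anyNA(idx))
    .stopf("unknown node(s): %s", paste(nodes[is.na(idx)], collapse = ", "))
  stats::setNames(as.character(object@networks[idx]), nodes)
})

setMethod("show", "NetworkPartition", function(object) {
  sz <- networkSizes(object)
  cat(sprintf("NetworkPartition: %d nodes in %d networks\n",
              length(object@nodeIds), length(sz)))
  cat(paste(sprintf("%s(%d)", names(sz), sz), collapse = " "), "\n")
})

## ---- CohortSpec ----

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d subjects x %d time points, %d nodes in %d networks\n",
              object@nSubjects, object@tPoints, sum(object@partitionSizes),
              length(object@partitionSizes)))
  co <- object@mediationCoeffs
  cat(sprintf("  planted paths: a = %.3g, b = %.3g, c' = %.3g; seed = %d\n",
              co["a"], co["b"], co["cPrime"], object@seed))
})

#' @rdname elsnet-accessors
setMethod("networkNames", "CohortSpec", function(object) names(object@partitionSizes))

#' @rdname elsnet-accessors
setMethod("networkSizes", "CohortSpec", function(object) object@partitionSizes)

## ---- ConnectivityExperiment ----

#' @rdname elsnet-accessors
setMethod("connectivityValues", "ConnectivityExperiment", function(object)
  SummarizedExperiment::assay(object, "connectivity"))

#' @rdname elsnet-accessors
setMethod("measureType", "ConnectivityExperiment", function(object)
  as.character(SummarizedExperiment::rowData(object)$measure_type))

#' @rdname elsnet-accessors
setMethod("networkNames", "ConnectivityExperiment", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  unique(stats::na.omit(c(as.character(rd$network_a), as.character(rd$network_b))))
})

## ---- FoldAssignment ----

#' @rdname elsnet-accessors
setMethod("foldOf", "FoldAssignment", function(object) object@fold)

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d subjects in %d balanced folds (sizes: %s)\n",
              length(object@fold), object@k,
              paste(tabulate(object@fold, object@k), collapse = ", ")))
})

## ---- PredictionResult ----

#' @rdname elsnet-accessors
setMethod("rPredObs", "PredictionResult", function(object) object@rPredObs)

#' @rdname elsnet-accessors
setMethod("predictions", "PredictionResult", function(object) object@predictions)

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %d-fold balanced CV linear SVR (C = %g, epsilon = %g)\n",
              object@folds@k, object@cost, object@epsilon))
  cat(sprintf("  n = %d, r(predicted, observed) = %.4f\n",
              length(object@predictions), object@rPredObs))
})

## ---- MediationResult ----

#' @rdname elsnet-accessors
setMethod("pathCoefficients", "MediationResult", function(object) object@paths)

#' @rdname elsnet-accessors
setMethod("indirectEffect", "MediationResult", function(object) object@indirect)

#' @rdname elsnet-accessors
setMethod("isSignificant", "MediationResult", function(object) object@significant)

#' @describeIn elsnet-accessors bootstrap CI of the indirect effect.
#' @param parm,level,... ignored (the CI level is fixed when the bootstrap
#'   is run).
#' @export
setMethod("confint", "MediationResult", function(object, parm, level, ...) {
  out <- matrix(c(object@ciLow, object@ciHigh), nrow = 1,
                dimnames = list("indirect", c("lower", "upper")))
  out
})

setMethod("show", "MediationResult", function(object) {
  p <- object@paths
  star <- if (object@significant) " *" else ""
  cat("MediationResult (standardized paths, case-resampling bootstrap)\n")
  cat(sprintf("      a = %+.4f      b = %+.4f\n", p["a"], p["b"]))
  cat(sprintf("  X ----------------------------> Y   c = %+.4f, c' = %+.4f\n",
              p["c"], p["cPrime"]))
  cat(sprintf("  indirect (a*b) = %+.4f, %d%% %s CI [%.4f, %.4f]%s\n",
              object@indirect, round(100 * object@ciLevel),
              ifelse(object@method == "bias_corrected", "BC", "percentile"),
              object@ciLow, object@ciHigh, star))
  cat(sprintf("  n_boot = %d, z0 = %.4f, redraws = %d\n",
              object@nBoot, object@z0, object@nRedraws))
  if (object@pathological)
    cat("  note: pathological bootstrap distribution flagged\n")
})
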
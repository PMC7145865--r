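## End-to-end orchestration: synthesize or load a cohort, profile it, screen
## connectivity against ELS, estimate prediction accuracy, fit the mediation
## models, score the dot-probe task, and write every intermediate table plus
## a manifest.

#' Assemble a validated analysis configuration
#'
#' A plain serializable list gathering every tunable of the pipeline. A
#' run is a pure function of `(config, seed)`: rerunning with the same
#' configuration reproduces the outputs.
#'
#' @param cohort a [CohortSpec-class] (or `NULL` when `timeSeriesFiles` and
#'   `behaviorFile` point at user data).
#' @param dotProbe optional [DotProbeSpec-class] (or `NULL` to skip the
#'   attention-bias arm; or `trialsFile` for user data).
#' @param timeSeriesFiles,behaviorFile,partitionFile,trialsFile optional
#'   paths to user-supplied inputs in the documented dialects.
#' @param diagonalPolicy,fisherZ connectivity options (see
#'   [withinNetworkConnectivity()]).
#' @param target behavioral score screened against (default `"els"`).
#' @param screenCovariates,mediationCovariates covariate sets (see
#'   [covariatePreset()]).
#' @param q FDR level of the screen.
#' @param k,C,epsilon,nPerm prediction settings (see [cvPredict()] and
#'   [permutationPvalue()]).
#' @param nBoot,ciLevel,mediationMethod mediation settings (see
#'   [bootstrapIndirect()]).
#' @param mediatorMeasure connectivity measure used as the brain mediator
#'   (and, for synthetic cohorts, as the realized mediator that the planted
#'   exposure is coupled to); default `"within_VAN"`.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param outputDir directory for result tables (`NULL` keeps results in
#'   memory only).
#' @return a list of class `"elsnet_config"`.
#' @export
analysisConfig <- function(cohort = cohortSpec(), dotProbe = NULL,
                           timeSeriesFiles = NULL, behaviorFile = NULL,
                           partitionFile = NULL, trialsFile = NULL,
                           diagonalPolicy = "literal", fisherZ = FALSE,
                           target = "els",
                           screenCovariates = covariatePreset("age_sex"),
                           mediationCovariates = covariatePreset("age_sex"),
                           q = 0.05, k = 4, C = 1, epsilon = 0.1, nPerm = 199,
                           nBoot = 2000, ciLevel = 0.95,
                           mediationMethod = "bias_corrected",
                           mediatorMeasure = "within_VAN",
                           seed = 1L, outputDir = NULL) {
  cfg <- list(cohort = cohort, dotProbe = dotProbe,
              timeSeriesFiles = timeSeriesFiles, behaviorFile = behaviorFile,
              partitionFile = partitionFile, trialsFile = trialsFile,
              diagonalPolicy = diagonalPolicy, fisherZ = fisherZ,
              target = target, screenCovariates = screenCovariates,
              mediationCovariates = mediationCovariates, q = q, k = k, C = C,
              epsilon = epsilon, nPerm = nPerm, nBoot = nBoot,
              ciLevel = ciLevel, mediationMethod = mediationMethod,
              mediatorMeasure = mediatorMeasure,
              seed = as.integer(seed), outputDir = outputDir)
  if (is.null(cfg$cohort) && is.null(cfg$timeSeriesFiles))
    .stopf("either a CohortSpec or timeSeriesFiles must be supplied")
  class(cfg) <- "elsnet_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

# JSON-serializable view of a config (S4 specs flattened to lists); the
# output directory is not part of a run's identity
.configJson <- function(cfg) {
  cfg$outputDir <- NULL
  enc <- lapply(unclass(cfg), function(v) {
    if (is(v, "CohortSpec"))
      list(nSubjects = v@nSubjects, tPoints = v@tPoints,
           partitionSizes = as.list(v@partitionSizes),
           withinTargets = as.list(v@withinTargets),
           betweenTargets = as.vector(v@betweenTargets),
           mediationCoeffs = as.list(v@mediationCoeffs),
           noiseSd = v@noiseSd, perturbSd = v@perturbSd,
           nuisanceLoadings = as.list(v@nuisanceLoadings), seed = v@seed)
    else if (is(v, "DotProbeSpec"))
      list(nSubjects = v@nSubjects,
           trialsPerCondition = as.list(v@trialsPerCondition),
           nBlocks = v@nBlocks, baseRtMs = v@baseRtMs,
           biasShiftMs = as.list(v@biasShiftMs), biasSdMs = v@biasSdMs,
           rtNoiseSdMs = v@rtNoiseSdMs, errorRate = v@errorRate, seed = v@seed)
    else v
  })
  jsonlite::toJSON(enc, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full analysis pipeline
#'
#' Executes connectivity profiling, the ELS screen, the prediction analysis,
#' the mediation models and (when a dot-probe arm is configured) the
#' attention-bias scoring, on synthetic or user data. With synthetic data
#' the behavioral table is generated after profiling so that the planted
#' mediator is the realized within-network VAN connectivity. Prediction
#' features are the screen-significant measures (all measures when none
#' survive, so a null cohort still yields a permutation-calibrated r).
#'
#' When `config$outputDir` is set, writes `profiles.csv`, `behavior.csv`,
#' `screen.csv`, `predictions.csv`, `prediction.json`, `mediation.json`,
#' `bias_scores.csv` (if applicable) and `manifest.json`; any stage error
#' aborts with the stage name while earlier outputs are retained.
#'
#' @param config a configuration from [analysisConfig()].
#' @return list with elements `experiment`, `screen`, `prediction`
#'   (`list(result, p, rPermuted)`), `mediation` (list of
#'   [MediationResult-class]), `biasScores` (or `NULL`), and `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "elsnet_config"))
  partition <- .stage("partition", {
    if (!is.null(config$partitionFile)) readPartition(config$partitionFile)
    else defaultPartition(networkSizes(config$cohort))
  })
  ts <- .stage("timeseries", {
    if (!is.null(config$timeSeriesFiles)) config$timeSeriesFiles
    else simulateCohort(config$cohort)
  })
  experiment <- .stage("connectivity",
    profileCohort(ts, partition, config$diagonalPolicy, config$fisherZ))

  biasScores <- NULL
  trials <- NULL
  if (!is.null(config$trialsFile)) {
    trials <- .stage("dotprobe", readTrials(config$trialsFile))
  } else if (!is.null(config$dotProbe)) {
    trials <- .stage("dotprobe", simulateDotProbe(config$dotProbe))
  }
  if (!is.null(trials))
    biasScores <- .stage("dotprobe", scoreCohort(filterTrials(trials)))

  behavior <- .stage("behavior", {
    if (!is.null(config$behaviorFile)) readBehavior(config$behaviorFile)
    else simulateBehavior(config$cohort,
                          mValues = connectivityValues(experiment)[config$mediatorMeasure, ])
  })
  experiment <- .stage("behavior", {
    cd <- behavior[match(colnames(experiment), behavior$subject_id), , drop = FALSE]
    if (anyNA(cd$subject_id))
      .stopf("behavior table is missing subject(s): %s",
             paste(setdiff(colnames(experiment), behavior$subject_id), collapse = ", "))
    SummarizedExperiment::colData(experiment) <- S4Vectors::DataFrame(
      cd, row.names = cd$subject_id)
    experiment
  })

  screen <- .stage("screen",
    screenConnectivity(experiment, target = config$target,
                       covariates = config$screenCovariates, q = config$q))

  prediction <- .stage("prediction", {
    feats <- screen$measure[screen$significant]
    if (!length(feats)) feats <- screen$measure
    X <- t(connectivityValues(experiment))[, feats, drop = FALSE]
    cd <- as.data.frame(SummarizedExperiment::colData(experiment))
    y <- cd[[config$target]]
    covs <- if (length(config$screenCovariates))
      as.matrix(cd[, config$screenCovariates, drop = FALSE]) else NULL
    perm <- permutationPvalue(X, y, covs, k = config$k, C = config$C,
                              epsilon = config$epsilon, nPerm = config$nPerm,
                              seed = childSeed(config$seed, 20L))
    res <- cvPredict(X, y, covs, k = config$k, C = config$C,
                     epsilon = config$epsilon, seed = childSeed(config$seed, 20L))
    list(result = res, features = feats, p = perm$p, rPermuted = perm$rPermuted)
  })

  mediation <- .stage("mediation",
    runMediationModels(experiment, biasScores = biasScores,
                       covariates = config$mediationCovariates,
                       mediatorMeasure = config$mediatorMeasure,
                       nBoot = config$nBoot, ciLevel = config$ciLevel,
                       method = config$mediationMethod,
                       seed = childSeed(config$seed, 30L)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("elsnet")),
    seed = config$seed,
    config_checksum = .checksum(as.character(.configJson(config))),
    n_subjects = ncol(experiment),
    n_measures = nrow(experiment),
    artifacts = character(0))

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    outs <- character(0)
    wp <- function(fn, writer) {
      path <- file.path(config$outputDir, fn)
      writer(path)
      outs <<- c(outs, fn)
    }
    wp("profiles.csv", function(p) writeProfiles(experiment, p))
    wp("behavior.csv", function(p) writeBehavior(behavior, p))
    wp("screen.csv", function(p) utils::write.csv(screen, p, row.names = FALSE))
    wp("predictions.csv", function(p) utils::write.csv(
      data.frame(subject_id = colnames(experiment),
                 observed = prediction$result@observed,
                 predicted = prediction$result@predictions,
                 fold = foldOf(prediction$result@folds)),
      p, row.names = FALSE))
    wp("prediction.json", function(p) jsonlite::write_json(
      list(r_pred_obs = rPredObs(prediction$result), p = prediction$p,
           k = config$k, C = config$C, epsilon = config$epsilon,
           n_perm = config$nPerm, features = prediction$features),
      p, auto_unbox = TRUE, digits = NA))
    wp("mediation.json", function(p) jsonlite::write_json(
      lapply(mediation, function(mr) list(
        paths = as.list(pathCoefficients(mr)),
        indirect = indirectEffect(mr), ci = c(mr@ciLow, mr@ciHigh),
        n_boot = mr@nBoot, ci_level = mr@ciLevel, method = mr@method,
        significant = isSignificant(mr))),
      p, auto_unbox = TRUE, digits = NA))
    if (!is.null(biasScores))
      wp("bias_scores.csv", function(p) utils::write.csv(biasScores, p, row.names = FALSE))
    manifest$artifacts <- outs
    jsonlite::write_json(manifest, file.path(config$outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(experiment = experiment, screen = screen, prediction = prediction,
       mediation = mediation, biasScores = biasScores, manifest = manifest)
}

#' Replication of the connectivity screen in a second cohort
#'
#' Runs the ELS screen on two cohorts and reports which associations
#' replicate: same sign and significant (FDR-surviving) in both.
#'
#' @param config,secondConfig configurations from [analysisConfig()].
#' @return list with `screen1`, `screen2` and `replication` (a `data.frame`
#'   over the shared measures with per-cohort r and significance and a
#'   `replicated` flag).
#' @export
replicateScreen <- function(config, secondConfig) {
  run1 <- runPipeline(config)
  run2 <- runPipeline(secondConfig)
  s1 <- run1$screen; s2 <- run2$screen
  shared <- intersect(s1$measure, s2$measure)
  if (!length(shared)) .stopf("the two cohorts share no connectivity measures")
  i1 <- match(shared, s1$measure); i2 <- match(shared, s2$measure)
  rep <- data.frame(
    measure = shared,
    r1 = s1$r[i1], significant1 = s1$significant[i1],
    r2 = s2$r[i2], significant2 = s2$significant[i2],
    stringsAsFactors = FALSE)
  rep$replicated <- rep$significant1 & rep$significant2 &
    sign(rep$r1) == sign(rep$r2)
  list(screen1 = s1, screen2 = s2, replication = rep)
}
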
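## Dot-probe attention-bias scoring from trial-level reaction times.

.CONDITIONS <- c("NH", "NS", "NA", "NF")

.validateTrials <- function(trials) {
  need <- c("subject_id", "condition", "face_side", "probe_side", "rt_ms", "correct")
  miss <- setdiff(need, colnames(trials))
  if (length(miss))
    .stopf("trial table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(trials$condition) || !all(trials$condition %in% .CONDITIONS))
    .stopf("condition must be one of %s", paste(.CONDITIONS, collapse = ", "))
  if (!all(trials$face_side %in% c("L", "R")) ||
      !all(trials$probe_side %in% c("L", "R")))
    .stopf("face_side and probe_side must be 'L' or 'R'")
  if (any(!is.finite(trials$rt_ms)) || any(trials$rt_ms <= 0))
    .stopf("rt_ms must be positive")
  invisible(trials)
}

#' Filter dot-probe trials
#'
#' Conventional dot-probe trial hygiene: removes incorrect trials, removes
#' reaction times outside `[rtMinMs, rtMaxMs]`, and optionally clips trials
#' beyond `sdClip` standard deviations of each subject's mean RT (computed
#' after the first two rules). Counts removed per rule are attached as the
#' `"filterCounts"` attribute; subject-condition cells left empty are listed
#' in the `"emptyCells"` attribute and flagged with a warning, not an error.
#'
#' @param trials trial `data.frame` (see [simulateDotProbe()] for columns).
#' @param rtMinMs,rtMaxMs inclusive RT window in ms (defaults 200 and 1500).
#' @param sdClip optional k for a per-subject +/- k SD clip (default none).
#' @return the filtered trial table.
#' @export
filterTrials <- function(trials, rtMinMs = 200, rtMaxMs = 1500, sdClip = NULL) {
  .validateTrials(trials)
  if (rtMinMs <= 0 || rtMaxMs <= 0 || rtMinMs >= rtMaxMs)
    .stopf("RT bounds must be positive with rtMinMs < rtMaxMs")
  before <- table(trials$subject_id, trials$condition)
  nIncorrect <- sum(!trials$correct)
  out <- trials[trials$correct, , drop = FALSE]
  inRange <- out$rt_ms >= rtMinMs & out$rt_ms <= rtMaxMs
  nRange <- sum(!inRange)
  out <- out[inRange, , drop = FALSE]
  nClip <- 0L
  if (!is.null(sdClip)) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$subject_id), function(i) {
      mu <- mean(out$rt_ms[i]); s <- stats::sd(out$rt_ms[i])
      if (!is.finite(s) || s == 0) return(i)
      i[abs(out$rt_ms[i] - mu) <= sdClip * s]
    }), use.names = FALSE)
    nClip <- nrow(out) - length(keep)
    out <- out[sort(keep), , drop = FALSE]
  }
  after <- table(factor(out$subject_id, levels = rownames(before)),
                 factor(out$condition, levels = colnames(before)))
  emptied <- which(before > 0 & after == 0, arr.ind = TRUE)
  empty <- data.frame(subject_id = rownames(before)[emptied[, 1L]],
                      condition = colnames(before)[emptied[, 2L]],
                      stringsAsFactors = FALSE)
  if (nrow(empty))
    .warnf("%d subject-condition cell(s) lost all trials during filtering",
           nrow(empty))
  rownames(out) <- NULL
  attr(out, "filterCounts") <- c(incorrect = nIncorrect, rt_range = nRange,
                                 sd_clip = nClip)
  attr(out, "emptyCells") <- empty
  out
}

#' Attention-bias score for one emotion condition
#'
#' Computes, per subject, \deqn{\textrm{bias} = \frac{1}{2}[(RpLe - RpRe) +
#' (LpRe - LpLe)],} where `XpYe` is the mean reaction time with the probe on
#' side X and the emotional face on side Y. The score equals the mean
#' incongruent-trial RT minus the mean congruent-trial RT: positive values
#' indicate attention allocated toward the emotional face, negative values
#' attention away from it (avoidance). Subjects missing any of the four
#' (probe, face) cells get a missing score with the reason recorded.
#'
#' @param trials filtered trial table (see [filterTrials()]).
#' @param emotion condition label (one of NH, NS, NA, NF).
#' @param statistic per-cell location statistic: `"mean"` (default) or
#'   `"median"`.
#' @return `data.frame` with one row per subject: `subject_id, emotion,
#'   bias_ms, n_RpLe, n_RpRe, n_LpRe, n_LpLe, missing, reason`.
#' @export
biasScore <- function(trials, emotion, statistic = c("mean", "median")) {
  .validateTrials(trials)
  emotion <- match.arg(emotion, .CONDITIONS)
  statistic <- match.arg(statistic)
  loc <- if (statistic == "mean") mean else stats::median
  tr <- trials[trials$condition == emotion, , drop = FALSE]
  subjects <- unique(trials$subject_id)
  cellMean <- function(d, probe, face) {
    v <- d$rt_ms[d$probe_side == probe & d$face_side == face]
    c(mean = if (length(v)) loc(v) else NA_real_, n = length(v))
  }
  rows <- lapply(subjects, function(s) {
    d <- tr[tr$subject_id == s, , drop = FALSE]
    RpLe <- cellMean(d, "R", "L"); RpRe <- cellMean(d, "R", "R")
    LpRe <- cellMean(d, "L", "R"); LpLe <- cellMean(d, "L", "L")
    ns <- c(RpLe["n"], RpRe["n"], LpRe["n"], LpLe["n"])
    missing <- any(ns == 0)
    bias <- if (missing) NA_real_ else
      0.5 * ((RpLe["mean"] - RpRe["mean"]) + (LpRe["mean"] - LpLe["mean"]))
    data.frame(subject_id = s, emotion = emotion, bias_ms = unname(bias),
               n_RpLe = ns[1L], n_RpRe = ns[2L], n_LpRe = ns[3L], n_LpLe = ns[4L],
               missing = missing,
               reason = if (missing) "empty (probe, face) cell" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attention-bias scores for a cohort across emotion conditions
#'
#' @param trials filtered trial table.
#' @param emotions conditions to score (default all four).
#' @inheritParams biasScore
#' @return tidy `data.frame`, one row per subject x emotion, with explicit
#'   missingness flags (see [biasScore()]).
#' @export
scoreCohort <- function(trials, emotions = .CONDITIONS,
                        statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  out <- do.call(rbind,
                 lapply(emotions, function(e) biasScore(trials, e, statistic)))
  rownames(out) <- NULL
  out
}
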
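# build a small trial table by hand: one subject unless stated otherwise
makeTrials <- function(rt, probe, face, condition = "NS", correct = TRUE,
                       subject = "S001") {
  data.frame(subject_id = subject, block = 1L, condition = condition,
             face_side = face, probe_side = probe, rt_ms = rt,
             correct = correct, stringsAsFactors = FALSE)
}

# the four cells, two trials each, with given cell means
cellTrials <- function(RpLe, RpRe, LpRe, LpLe, subject = "S001") {
  rbind(makeTrials(c(RpLe - 1, RpLe + 1), "R", "L", subject = subject),
        makeTrials(c(RpRe - 1, RpRe + 1), "R", "R", subject = subject),
        makeTrials(c(LpRe - 1, LpRe + 1), "L", "R", subject = subject),
        makeTrials(c(LpLe - 1, LpLe + 1), "L", "L", subject = subject))
}

test_that("the bias score implements the four-cell contrast", {
  # equal cell means cancel
  expect_equal(biasScore(cellTrials(500, 500, 500, 500), "NS")$bias_ms, 0)
  # congruent 480 / incongruent 500: bias +20
  expect_equal(biasScore(cellTrials(500, 480, 500, 480), "NS")$bias_ms, 20)
  # direct substitution: (510, 495, 505, 490) -> 15
  expect_equal(biasScore(cellTrials(510, 495, 505, 490), "NS")$bias_ms, 15)
})

test_that("bias scores obey the label-swap and location invariances", {
  set.seed(1)
  tr <- simulateDotProbe(dotProbeSpec(nSubjects = 4, biasShiftMs = 12, seed = 3))
  base <- scoreCohort(tr)
  # adding a constant to all RTs changes nothing
  shifted <- tr; shifted$rt_ms <- shifted$rt_ms + 250
  expect_equal(scoreCohort(shifted)$bias_ms, base$bias_ms)
  # swapping both face and probe labels changes nothing
  both <- tr
  both$face_side <- chartr("LR", "RL", both$face_side)
  both$probe_side <- chartr("LR", "RL", both$probe_side)
  expect_equal(scoreCohort(both)$bias_ms, base$bias_ms)
  # swapping only the face label negates every score
  faceOnly <- tr
  faceOnly$face_side <- chartr("LR", "RL", faceOnly$face_side)
  expect_equal(scoreCohort(faceOnly)$bias_ms, -base$bias_ms)
})

test_that("trial filtering applies each rule and keeps bookkeeping", {
  tr <- cellTrials(510, 495, 505, 490)
  # identity on clean input
  clean <- filterTrials(tr)
  expect_equal(nrow(clean), nrow(tr))
  expect_identical(unname(attr(clean, "filterCounts")),
                   c(0L, 0L, 0L))
  # one anticipatory 50 ms trial is removed by the RT floor alone
  tr2 <- rbind(tr, makeTrials(50, "R", "L"))
  f2 <- filterTrials(tr2, rtMinMs = 200)
  expect_equal(nrow(f2), nrow(tr))
  expect_identical(unname(attr(f2, "filterCounts")["rt_range"]), 1L)
  # planted errors are removed and counted exactly
  set.seed(2)
  sp <- dotProbeSpec(nSubjects = 3, errorRate = 0.05, seed = 5)
  tr3 <- simulateDotProbe(sp)
  f3 <- filterTrials(tr3)
  expect_identical(unname(attr(f3, "filterCounts")["incorrect"]),
                   sum(!tr3$correct))
  # the SD clip removes extreme trials only
  tr4 <- rbind(tr, makeTrials(1400, "R", "L"))
  f4 <- filterTrials(tr4, sdClip = 2)
  expect_identical(unname(attr(f4, "filterCounts")["sd_clip"]), 1L)
  expect_error(filterTrials(tr, rtMinMs = 500, rtMaxMs = 100), "rtMinMs < rtMaxMs")
})

test_that("the median statistic resists a single outlier trial", {
  tr <- cellTrials(510, 495, 505, 490)
  tr <- rbind(tr, makeTrials(1200, "R", "L"))  # outlier in the RpLe cell
  # median of {509, 511, 1200} is 511, so the cell contributes 511 - 495
  expect_equal(biasScore(tr, "NS", statistic = "median")$bias_ms, 15.5)
  expect_gt(biasScore(tr, "NS", statistic = "mean")$bias_ms, 100)
})

test_that("missing cells yield flagged missing scores, not failures", {
  tr <- cellTrials(510, 495, 505, 490)
  tr <- tr[!(tr$probe_side == "R" & tr$face_side == "L"), ]
  out <- biasScore(tr, "NS")
  expect_true(out$missing)
  expect_true(is.na(out$bias_ms))
  expect_match(out$reason, "cell")
  # a subject losing all correct NS trials keeps other conditions intact
  two <- rbind(cellTrials(500, 500, 500, 500, subject = "S001"),
               cellTrials(520, 500, 520, 500, subject = "S002"))
  two$condition[two$subject_id == "S002"] <- "NH"
  sc <- scoreCohort(two, emotions = c("NS", "NH"))
  expect_true(sc$missing[sc$subject_id == "S002" & sc$emotion == "NS"])
  expect_false(sc$missing[sc$subject_id == "S002" & sc$emotion == "NH"])
  expect_equal(sc$bias_ms[sc$subject_id == "S002" & sc$emotion == "NH"], 20)
})

test_that("planted per-emotion shifts are recovered within sampling error", {
  set.seed(3)
  sp <- dotProbeSpec(nSubjects = 60,
                     biasShiftMs = c(NH = 0, NS = 20, "NA" = -10, NF = 0),
                     biasSdMs = 0, rtNoiseSdMs = 60, errorRate = 0.05, seed = 7)
  sc <- scoreCohort(filterTrials(simulateDotProbe(sp)))
  for (cond in c("NH", "NS", "NA", "NF")) {
    v <- sc$bias_ms[sc$emotion == cond]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - sp@biasShiftMs[[cond]]), 3.5 * se + 1)
  }
})
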
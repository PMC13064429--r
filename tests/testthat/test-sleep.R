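featRow <- function(deltaFrac = 0.2, thetaDelta = 1, emgZ = 0,
                    activity = 0, artifactFrac = 0) {
  data.frame(epoch = 1, deltaFrac = deltaFrac, thetaDelta = thetaDelta,
             emgZ = emgZ, activity = activity, artifactFrac = artifactFrac,
             valid = TRUE)
}

test_that("the staging rule fires in the declared order", {
  ## activity forces wake regardless of EEG
  expect_equal(scoreEpochs(featRow(deltaFrac = 0.9, activity = 3)), "wake")
  ## distinct EMG forces wake
  expect_equal(scoreEpochs(featRow(deltaFrac = 0.9, emgZ = 2)), "wake")
  ## no activity + slow waves + quiet EMG -> NREM
  expect_equal(scoreEpochs(featRow(deltaFrac = 0.6, emgZ = -0.5)), "NREM")
  ## no activity + theta-dominated + quiet EMG -> REM
  expect_equal(scoreEpochs(featRow(deltaFrac = 0.2, thetaDelta = 2,
                                   emgZ = -0.5)), "REM")
  ## artifact cutoff 0.5 for sleep candidates...
  expect_equal(scoreEpochs(featRow(deltaFrac = 0.6, emgZ = -0.5,
                                   artifactFrac = 0.6)), "artifact")
  ## ...but 0.8 for wake candidates: only large artifacts mark wake
  expect_equal(scoreEpochs(featRow(activity = 3, artifactFrac = 0.6)), "wake")
  expect_equal(scoreEpochs(featRow(activity = 3, artifactFrac = 0.85)),
               "artifact")
  ## indeterminate epochs carry the previous stage (wake at the start)
  f2 <- rbind(featRow(deltaFrac = 0.6, emgZ = -0.5),
              featRow(deltaFrac = 0.3, thetaDelta = 1, emgZ = 0.2))
  expect_equal(scoreEpochs(f2), c("NREM", "NREM"))
  expect_equal(scoreEpochs(featRow(deltaFrac = 0.3, emgZ = 0.2)), "wake")
})

test_that("the majority rule picks the modal stage with rule-order ties", {
  expect_equal(majorityStage(c(rep("wake", 6), rep("NREM", 4))), "wake")
  expect_equal(majorityStage(c(rep("NREM", 5), rep("REM", 5))), "NREM")
  expect_equal(majorityStage(rep("REM", 10)), "REM")
  expect_equal(majorityStage(c(rep("artifact", 5), rep("wake", 5))), "artifact")
  expect_error(majorityStage(character(0)))
})

test_that("the artifact exclusion bound is inclusive at 5%", {
  mk <- function(nArt, n = 8640) c(rep("artifact", nArt), rep("wake", n - nArt))
  expect_false(artifactExclusion(mk(345))$excluded)   # ~4%
  ex <- artifactExclusion(mk(432))                     # exactly 5%
  expect_equal(ex$artifactFraction, 0.05)
  expect_true(ex$excluded)
  expect_equal(artifactExclusion(mk(0))$artifactFraction, 0)
})

test_that("bout statistics follow from the stage sequence", {
  ## alternating 30-epoch NREM / 30-epoch wake over 24 h (8640 epochs):
  ## 144 bouts of 5 min each
  stages <- rep(c(rep("NREM", 30), rep("wake", 30)), 144)
  s <- sleepSummary(stages)
  expect_equal(s$boutCount, 144)
  expect_equal(s$meanBoutMinutes, 5)
  ## all-wake day: no bouts, wake 100%
  s2 <- sleepSummary(rep("wake", 8640))
  expect_equal(s2$boutCount, 0)
  expect_equal(s2$percent$cycle[s2$percent$stage == "wake"], 100)
  ## runs shorter than 3 epochs are not bouts
  s3 <- sleepSummary(c(rep("wake", 5), rep("NREM", 2), rep("wake", 5)))
  expect_equal(s3$boutCount, 0)
})

test_that("day and night percentages reconstruct the cycle percentage", {
  sim <- simSmall()
  rep <- simSmallReport()
  p <- rep$sleep$percent
  nDay <- sum(eegtel:::inLightPhase(
    (6 + (seq_along(rep$hypnogram$stage) - 1) * 10 / 3600) %% 24, 6, 18))
  nNight <- nrow(rep$hypnogram) - nDay
  recon <- (p$day * nDay + p$night * nNight) / (nDay + nNight)
  expect_equal(recon, p$cycle, tolerance = 1e-9)
  expect_equal(sum(p$cycle), 100, tolerance = 1e-9)
})

test_that("staging recovers the hidden state sequence and is deterministic", {
  sim <- simSmall()
  rep <- simSmallReport()
  truth <- stateSequence(sim$truth)
  acc <- mean(rep$hypnogram$stage == truth)
  expect_gte(acc, 0.90)
  ## REM scarcer than NREM
  expect_lt(sum(rep$hypnogram$stage == "REM"),
            sum(rep$hypnogram$stage == "NREM"))
  ## determinism: rescoring the same features gives the same stages
  cl <- removeArtifacts(eeg(sim$recording), samplingRate = 500)
  fr <- spectrogramMedianBins(highpassFilter(cl$cleaned, 0.5, 500), 500,
                              mask = cl$mask)
  f <- epochFeatures(fr, emg(sim$recording), activity(sim$recording), 500)
  expect_identical(scoreEpochs(f), scoreEpochs(f))
  expect_identical(scoreEpochs(f), rep$hypnogram$stage)
})

test_that("minute activity is apportioned to epochs, zero minutes giving zero epochs", {
  rms <- c(rep(0.1, 3), rep(0.01, 3))   # first half of the minute noisy
  a <- eegtel:::apportionActivity(c(4), rms, 6)
  expect_equal(sum(a), 4)
  expect_true(all(a[4:6] <= a[1:3][a[1:3] > 0] | a[4:6] == 0))
  expect_equal(eegtel:::apportionActivity(c(0), rms, 6), rep(0, 6))
  expect_equal(eegtel:::apportionActivity(c(NA), rms, 6), rep(0, 6))
})

test_that("per-stage spectra separate delta-dominant NREM from wake", {
  rep <- simSmallReport()
  sp <- rep$sleep$stageSpectra
  freqs <- as.numeric(colnames(sp))
  deltaIdx <- freqs <= 4
  if (!anyNA(sp["NREM", ]) && !anyNA(sp["wake", ])) {
    deltaShare <- function(s) sum(s[deltaIdx]) / sum(s)
    expect_gt(deltaShare(sp["NREM", ]), deltaShare(sp["wake", ]))
  }
})
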
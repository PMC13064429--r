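test_that("identical configurations give bit-identical recordings", {
  cfg <- simConfig(durationHours = 1 / 3, rngSeed = 1,
                   spikeRates = c(A = 6, B = 6, C = 6), artifactRate = 6)
  a <- simulateRecording(cfg)
  b <- simulateRecording(cfg)
  expect_identical(eeg(a$recording), eeg(b$recording))
  expect_identical(emg(a$recording), emg(b$recording))
  expect_identical(activity(a$recording), activity(b$recording))
  expect_identical(stateSequence(a$truth), stateSequence(b$truth))
  expect_identical(spikeTruth(a$truth), spikeTruth(b$truth))
  expect_identical(artifactIntervals(a$truth), artifactIntervals(b$truth))
})

test_that("zero spike rates inject nothing", {
  sim <- simulateRecording(simConfig(durationHours = 1 / 3, rngSeed = 2))
  expect_identical(nrow(spikeTruth(sim$truth)), 0L)
  expect_identical(nrow(artifactIntervals(sim$truth)), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(durationHours = 5 / 60), "10 min")
  expect_error(simConfig(samplingRate = 150), "160 Hz")
  expect_error(simConfig(artifactAmplitudeMv = 1.5), "2 mV")
  expect_error(simConfig(spikeRates = c(A = -1, B = 0, C = 0)), "non-negative")
  expect_error(makeSpikeTemplate("D", 500), "unknown spike class")
})

test_that("ground-truth invariants hold: spikes inside the recording, disjoint artifacts, one state per epoch", {
  sim <- simulateRecording(simConfig(durationHours = 0.5, rngSeed = 7,
                                     spikeRates = c(A = 4, B = 4, C = 4),
                                     artifactRate = 8))
  dur <- durationHours(sim$recording) * 3600
  spk <- spikeTruth(sim$truth)
  expect_true(all(spk$time > 0 & spk$time < dur))
  ai <- artifactIntervals(sim$truth)
  if (nrow(ai) > 1)
    expect_true(all(ai$start[-1] >= ai$end[-nrow(ai)]))
  expect_length(stateSequence(sim$truth), 0.5 * 360)
})

test_that("spike templates have class-ordered morphology within the 15-70 ms waveform range", {
  fs <- 500
  m <- lapply(c(A = "A", B = "B", C = "C"), function(cl) {
    tpl <- makeSpikeTemplate(cl, fs)   # unitSd = 1, threshold at 10
    c(list(peak = max(abs(tpl)), nominal = attr(tpl, "nominalWidthMs")),
      eegtel:::templateMetrics(tpl, fs, 10))
  })
  ## nominal waveform durations all inside 15-70 ms
  for (cl in names(m)) {
    expect_gte(m[[cl]]$nominal, 15)
    expect_lte(m[[cl]]$nominal, 70)
    expect_gte(m[[cl]]$widthMs, 15)
    expect_lte(m[[cl]]$widthMs, 70)
  }
  ## class A: fast, large; <= 30 ms, peak >= 20 SD
  expect_lte(m$A$nominal, 30)
  expect_gte(m$A$peak, 20)
  expect_lte(m$A$halfDecayMs, 15)
  ## class C: slowest, smallest admissible peak, 40-70 ms waveform
  expect_gte(m$C$nominal, 40)
  expect_lte(m$C$nominal, 70)
  expect_gte(m$C$halfDecayMs, 30)
  expect_lt(m$C$peak, 12)
  ## orderings
  expect_true(m$A$peak > m$B$peak && m$B$peak > m$C$peak)
  expect_true(m$A$halfDecayMs < m$B$halfDecayMs &&
                m$B$halfDecayMs < m$C$halfDecayMs)
})

test_that("single-state simulation concentrates power in the enabled band at the expected level", {
  sim <- simNrem()
  frames <- simNremFrames()
  bp <- eegtel:::frameBandPower(frames, defaultBands())
  means <- colMeans(bp)
  ## integrated delta power matches the closed-form A^2/2 within 10%
  ## (the pink background adds a few percent)
  expectDelta <- sim$truth@bandPowerExpectation["NREM", "delta"]
  expect_lt(abs(means[["delta"]] - expectDelta) / expectDelta, 0.10)
  ## spectral fidelity: the enabled band dominates every other band >= 5x
  expect_true(all(means[["delta"]] >= 5 * means[names(means) != "delta"]))
})

test_that("activity counts are zero during sleep and Poisson-calibrated during wake", {
  simN <- simNrem()
  expect_true(all(activity(simN$recording) == 0))
  ## wake-only, light phase: per-minute counts ~ Poisson(3); over many
  ## minutes the mean lies within 3 standard errors of the rate
  simW <- simulateRecording(simConfig(durationHours = 1, rngSeed = 6,
                                      fixedState = "wake"))
  counts <- activity(simW$recording)
  se <- sqrt(3 / length(counts))
  expect_lt(abs(mean(counts) - 3), 3 * se + 1e-12)
})

test_that("injected spike counts are Poisson with the configured rate", {
  ## 40 replicate simulations at 60 events/h for 10 min each: the
  ## empirical mean count must lie within 3 SE of the expectation (10)
  counts <- vapply(1:40, function(s) {
    sim <- simulateRecording(simConfig(durationHours = 1 / 6, rngSeed = 100 + s,
                                       spikeRates = c(A = 0, B = 60, C = 0)))
    nrow(spikeTruth(sim$truth))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 40))
})

test_that("injectArtifacts respects its contract", {
  fs <- 500
  x <- rnorm(fs * 10, sd = 0.05)
  expect_identical(injectArtifacts(x, data.frame(start = numeric(0),
                                                 end = numeric(0)),
                                   3, fs), x)
  y <- injectArtifacts(x, data.frame(start = 2, end = 3), 3, fs)
  over <- abs(y) > 2
  expect_equal(sum(over), fs)                 # exactly the 1 s interval
  expect_true(all(which(over) >= 2 * fs + 1 & which(over) <= 3 * fs))
  expect_identical(y[1:(2 * fs - 1)], x[1:(2 * fs - 1)])
  expect_error(injectArtifacts(x, data.frame(start = 2, end = 3), 1.5, fs),
               "exceed")
  expect_error(injectArtifacts(x, data.frame(start = 9, end = 11), 3, fs),
               "within")
})

test_that("REM is entered only from NREM in the hidden state sequence", {
  sim <- simulateRecording(simConfig(durationHours = 2, rngSeed = 9))
  st <- stateSequence(sim$truth)
  entries <- which(st[-1] == "REM" & st[-length(st)] != "REM")
  expect_true(all(st[entries] == "NREM"))
})
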
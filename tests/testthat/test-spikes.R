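test_that("baseline SD estimation is consistent and spike-robust", {
  fs <- 500
  set.seed(21)
  x <- rnorm(fs * 120, sd = 0.05)
  s0 <- estimateBaselineSd(x, samplingRate = fs)
  expect_lt(abs(s0 - 0.05) / 0.05, 0.05)

  ## adding 1 spike/min at 15x SD moves the estimate by < 2%
  tpl <- makeSpikeTemplate("B", fs, amplitude = 15, unitSd = 0.05)
  xs <- injectWaveform(x, tpl, seq(30, 90, by = 60), fs)
  s1 <- estimateBaselineSd(xs, samplingRate = fs)
  expect_lt(abs(s1 - s0) / s0, 0.02)

  expect_error(estimateBaselineSd(rep(0, fs * 120), samplingRate = fs),
               "degenerate")
  expect_error(estimateBaselineSd(rnorm(fs * 10), samplingRate = fs),
               "one minute")
})

test_that("threshold detection finds injected transients and ignores sub-threshold ones", {
  fs <- 500
  set.seed(22)
  sd0 <- 0.05
  x <- rnorm(fs * 300, sd = sd0)
  tpl <- makeSpikeTemplate("B", fs, amplitude = 15, unitSd = sd0)
  at <- c(50, 150, 250)
  xs <- injectWaveform(x, tpl, at, fs)
  ev <- detectSpikes(xs, fs, sd0)
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(ev$time - at) <= 0.005))
  expect_true(all(ev$amplitude >= 10))

  ## an excursion at 9.5x SD is below threshold
  y <- numeric(fs * 10)
  y[fs * 5] <- 9.5 * sd0
  expect_equal(nrow(detectSpikes(y, fs, sd0)), 0)

  ## masked samples never trigger detection
  mask <- logical(length(xs)); mask[(149 * fs):(151 * fs)] <- TRUE
  ev2 <- detectSpikes(xs, fs, sd0, mask = mask)
  expect_equal(nrow(ev2), 2)
})

test_that("detection is monotone in the threshold", {
  fs <- 500
  set.seed(23)
  x <- rnorm(fs * 60, sd = 0.05)
  x <- injectWaveform(x, makeSpikeTemplate("A", fs, unitSd = 0.05), c(10, 30), fs)
  x <- injectWaveform(x, makeSpikeTemplate("C", fs, unitSd = 0.05), 50, fs)
  counts <- vapply(c(8, 10, 12, 25), function(k)
    nrow(detectSpikes(x, fs, 0.05, k = k)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the width filter keeps only 15-70 ms waveforms", {
  ev <- data.frame(time = 1:4, amplitude = c(15, 15, 15, 15),
                   widthMs = c(10, 15, 70, 100),
                   halfDecayMs = 20, start = 0, end = 1)
  kept <- filterByWidth(ev)
  expect_equal(kept$widthMs, c(15, 70))
})

test_that("classification follows the amplitude/half-decay rule and partitions events", {
  ev <- data.frame(time = 1:4,
                   amplitude = c(25, 11, 15, 25),
                   widthMs = 30,
                   halfDecayMs = c(10, 40, 20, 40),
                   start = 0, end = 1)
  cl <- classifySpikes(ev)
  expect_equal(cl$class, c("A", "C", "B", "B"))
  expect_true(all(cl$class %in% c("A", "B", "C")))
})

test_that("spike rates are per-class counts over unmasked hours and sum to the total", {
  ev <- data.frame(class = rep("B", 48))
  sr <- spikeRate(ev, analyzedHours = 24)
  expect_equal(sr$B, 2)
  expect_equal(sr$total, 2)
  expect_equal(sr$A + sr$B + sr$C, sr$total)

  ## empty event set
  sr0 <- spikeRate(ev[0, , drop = FALSE], 24)
  expect_equal(sr0$total, 0)

  ## masked time shrinks the denominator
  sr2 <- spikeRate(ev, 24, maskedHours = 12)
  expect_equal(sr2$total, 4)
  expect_error(spikeRate(ev, 1, maskedHours = 1), "analyzable")
})

test_that("end-to-end spike recovery on a high-SNR simulation", {
  ## all classes injected at >= 12x SD; the amplitude boundary sits
  ## above the injected C amplitude (peak measurement is noise-biased
  ## upward), leaving half-decay to separate B from C
  sim <- fixture("simSpikeUnit",
    simulateRecording(simConfig(durationHours = 2, rngSeed = 31,
                                spikeRates = c(A = 3, B = 3, C = 2),
                                spikeAmplitudes = c(A = 22, B = 15, C = 13))))
  rep <- fixture("simSpikeUnitReport",
                 analyzeSubject(sim$recording, pipelineParams(classAB = 16)))
  truth <- spikeTruth(sim$truth)
  m <- matchSpikeEvents(rep$spikes, truth)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.90)
  expect_gte(m$classAgreement, 0.90)
  ## per-class rates sum to the total rate
  expect_equal(rep$spikeSummary$A + rep$spikeSummary$B + rep$spikeSummary$C,
               rep$spikeSummary$total)
})
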
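test_that("a pure tone peaks at its frequency gridpoint in every frame", {
  fs <- 500
  x <- sin(2 * pi * 10 * seq(0, 30 - 1 / fs, by = 1 / fs))
  fr <- spectrogramMedianBins(x, fs)
  expect_length(fr$time, 3)
  expect_true(all(fr$freq[apply(fr$power, 1, which.max)] == 10))
  ## tone power recovered: A^2/2 integrated over the spectrum
  expect_equal(rowSums(fr$power) * fr$df, rep(0.5, 3), tolerance = 1e-6)
})

test_that("white-noise median spectrum is flat within 3x over 1-80 Hz", {
  fs <- 500
  set.seed(42)
  x <- rnorm(fs * 1000)
  fr <- spectrogramMedianBins(x, fs)
  medSpec <- apply(fr$power, 2, median)
  expect_lt(max(medSpec) / min(medSpec), 3)
})

test_that("the per-bin median resists a single contaminated window", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  xb <- x
  idx <- 1:(0.5 * fs)          # one 500 ms window of the 20
  xb[idx] <- xb[idx] + 20 * sin(2 * pi * 30 * t[idx])
  a <- spectrogramMedianBins(x, fs)
  b <- spectrogramMedianBins(xb, fs)
  expect_lt(max(abs(b$power - a$power)) / max(a$power), 0.05)
})

test_that("band powers integrate the density and minutes aggregate frames", {
  ## constant unit density: band power proportional to band width
  bands <- defaultBands()
  nf <- 40
  frames <- structure(list(
    time = seq(0, 110, by = 10), freq = seq(2, 80, by = 2),
    power = matrix(1, 12, nf), valid = rep(TRUE, 12),
    maskedFraction = rep(0, 12), binSec = 10, df = 2),
    class = "SpectralFrames")
  mp <- minuteBandPower(frames, bands)
  ## on the 2 Hz grid the bands hold 1, 2, 3, 8 and 26 gridpoints, so a
  ## flat density splits power in those proportions
  expect_equal(unname(unlist(mp[1, bands$band]) / mp$total[1]),
               c(1, 2, 3, 8, 26) / 40, tolerance = 1e-12)
  expect_equal(mp$total, rowSums(mp[, bands$band]))

  ## a minute whose frames are all invalid is flagged missing
  frames$valid[7:12] <- FALSE
  mp2 <- minuteBandPower(frames, bands)
  expect_true(mp2$missing[2])
  expect_true(is.na(mp2$total[2]))
})

test_that("band powers sum to total power for simulated data (conservation)", {
  mp <- simSmallReport()$minutePower
  ok <- !mp$missing
  relErr <- abs(rowSums(mp[ok, defaultBands()$band]) - mp$total[ok]) / mp$total[ok]
  expect_lt(max(relErr), 1e-3)
})

test_that("tenth-percentile normalization uses linear interpolation and is scale-invariant", {
  bands <- defaultBands()$band
  mp <- linearMinuteTable(100)
  mp$total <- 1:100          # known percentile: quantile(1:100, .1) = 10.9
  for (b in bands) mp[[b]] <- mp$total / 5
  nm <- normalizeToTenthPercentile(mp)
  expect_equal(attr(nm, "p10"), 10.9)
  expect_equal(unname(quantile(nm$total_norm, 0.1, type = 7)), 1)

  ## constant series: every normalized total is 1
  mp2 <- mp; mp2$total <- rep(7, 100)
  nm2 <- normalizeToTenthPercentile(mp2)
  expect_true(all(nm2$total_norm == 1))

  ## scaling raw power leaves normalized values unchanged
  mp3 <- mp
  for (b in c(bands, "total")) mp3[[b]] <- mp3[[b]] * 3.7
  nm3 <- normalizeToTenthPercentile(mp3)
  expect_equal(nm3$total_norm, nm$total_norm, tolerance = 1e-12)

  ## degenerate inputs
  expect_error(normalizeToTenthPercentile(mp[1:5, ]), "at least 10")
  mp0 <- mp; mp0$total <- rep(0, 100)
  expect_error(normalizeToTenthPercentile(mp0), "degenerate")
})

test_that("per-minute band percentages sum to 100 and reflect band dominance", {
  pct <- simSmallReport()$percentPower
  sums <- rowSums(pct$minutes[, defaultBands()$band])
  expect_true(all(abs(sums - 100) < 0.1))

  ## delta-only simulation: delta percentage above 80%
  mpN <- minuteBandPower(simNremFrames(), defaultBands())
  pctN <- percentTotalPower(mpN)
  expect_gt(pctN$average[["delta"]], 80)
})

test_that("activity regression recovers exact and noisy linear relationships", {
  mp <- linearMinuteTable(60, slope = 3, intercept = 2)
  reg <- bandActivityRegression(mp)
  expect_equal(reg$slope, rep(3, 5), tolerance = 1e-12)
  expect_equal(reg$intercept, rep(2, 5), tolerance = 1e-12)
  expect_equal(reg$r2, rep(1, 5), tolerance = 1e-12)

  ## constant power: zero slope, intercept at the constant
  mp2 <- linearMinuteTable(60, slope = 0, intercept = 5)
  reg2 <- bandActivityRegression(mp2)
  expect_equal(reg2$slope, rep(0, 5), tolerance = 1e-12)
  expect_equal(reg2$intercept, rep(5, 5), tolerance = 1e-12)

  ## constant activity is undefined
  mp3 <- linearMinuteTable(60)
  mp3$activity <- rep(2, 60)
  expect_error(bandActivityRegression(mp3), "distinct activity")

  ## noisy recovery: slope within 3 SE of the truth
  set.seed(11)
  mp4 <- linearMinuteTable(1000)
  mp4$activity <- rpois(1000, 3)
  for (b in defaultBands()$band)
    mp4[[b]] <- 10 - 0.5 * mp4$activity + rnorm(1000, sd = 1)
  mp4$total <- rowSums(mp4[, defaultBands()$band])
  reg4 <- bandActivityRegression(mp4)
  d <- reg4[reg4$band == "delta", ]
  expect_lt(abs(d$slope - (-0.5)), 3 * d$se)
})

test_that("activity levels pool at 10 and respect degenerate inputs", {
  mp <- linearMinuteTable(42)
  mp$activity <- 0:41 %% 21          # counts 0..20
  ab <- activityBinnedPower(mp)
  expect_equal(ab$level, 0:10)
  ## level 10 pools counts 10..20
  mp$delta <- mp$activity
  ab2 <- activityBinnedPower(mp)
  expect_equal(ab2$delta[ab2$level == 10], mean(10:20))

  mp0 <- linearMinuteTable(12)
  mp0$activity <- rep(0, 12)
  expect_equal(activityBinnedPower(mp0)$level, 0)
})

test_that("the delta-slope QC rule excludes only positive slopes", {
  reg <- data.frame(band = "delta", slope = -0.2, intercept = 1,
                    r2 = 0.5, se = 0.01, n = 100)
  expect_false(qcDeltaActivity(reg)$excluded)
  reg$slope <- 0.2
  qc <- qcDeltaActivity(reg)
  expect_true(qc$excluded)
  expect_match(qc$reason, "delta")
  ## combined report: artifact fraction at the 5% bound also excludes
  expect_true(qcReport("m1", -0.1, 0.05)$excluded)
  expect_false(qcReport("m1", -0.1, 0.049)$excluded)
})
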
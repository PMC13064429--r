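#' Median-power spectrogram in 10 s bins
#'
#' Splits the (cleaned, 0.5 Hz high-passed) EEG into consecutive 10 s
#' bins, computes the one-sided power spectral density of each
#' non-overlapping 500 ms window inside a bin (20 windows per bin), and
#' returns the per-frequency MEDIAN across windows, restricted to the
#' 0.5-80 Hz analysis range. The median makes each bin robust to a
#' minority of contaminated windows. Windows containing masked (artifact)
#' samples are dropped from the median; a bin with more than half of its
#' samples masked, or with no clean window, is marked invalid.
#'
#' @param x numeric EEG trace (mV), cleaned and high-pass filtered.
#' @param samplingRate sampling rate (Hz).
#' @param mask optional logical artifact mask (same length as `x`).
#' @param windowSec FFT window length (s); must divide the bin at least
#'   twice.
#' @param binSec bin length (s).
#' @param fmin,fmax analysis range (Hz); `fmax` must be below Nyquist.
#' @param taper `"none"` (plain periodogram, the default) or `"hann"`.
#' @return list of class `"SpectralFrames"` with `time` (bin starts, s),
#'   `freq` (Hz), `power` (bins x frequencies matrix, mV^2/Hz), `valid`
#'   (logical), `maskedFraction`, `binSec`, `df` (grid spacing, Hz).
#' @examples
#' fs <- 500
#' x <- sin(2 * pi * 10 * seq(0, 20 - 1/fs, by = 1/fs))
#' fr <- spectrogramMedianBins(x, fs)
#' fr$freq[apply(fr$power, 1, which.max)]  # peak at 10 Hz in every bin
#' @export
spectrogramMedianBins <- function(x, samplingRate, mask = NULL,
                                  windowSec = 0.5, binSec = 10,
                                  fmin = 0.5, fmax = 80,
                                  taper = c("none", "hann")) {
  taper <- match.arg(taper)
  wlen <- round(windowSec * samplingRate)
  nwin <- round(binSec / windowSec)
  if (nwin < 2) stop("window must divide into the bin at least twice")
  if (fmax >= samplingRate / 2) stop("fmax must be below the Nyquist frequency")
  binLen <- wlen * nwin
  nbins <- length(x) %/% binLen
  if (nbins < 1) stop("recording shorter than one spectrogram bin")
  used <- nbins * binLen
  if (is.null(mask)) mask <- logical(length(x))

  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * seq_len(wlen) / (wlen + 1)))
       else rep(1, wlen)
  s2 <- sum(w^2)
  freqAll <- (0:(wlen %/% 2)) * samplingRate / wlen
  keep <- which(freqAll >= fmin & freqAll <= fmax)
  nf <- length(keep)

  xm <- matrix(x[seq_len(used)], nrow = wlen)          # wlen x (nwin*nbins)
  badWin <- colSums(matrix(mask[seq_len(used)], nrow = wlen)) > 0
  maskedFraction <- colMeans(matrix(
    matrix(mask[seq_len(used)], nrow = binLen), nrow = binLen))

  ncols <- ncol(xm)
  psd <- matrix(NA_real_, nf, ncols)
  chunk <- 4096L
  for (st in seq(1L, ncols, by = chunk)) {
    en <- min(st + chunk - 1L, ncols)
    F <- stats::mvfft(xm[, st:en, drop = FALSE] * w)
    psd[, st:en] <- 2 * Mod(F[keep, , drop = FALSE])^2 / (samplingRate * s2)
  }
  rm(xm)

  power <- matrix(NA_real_, nbins, nf)
  valid <- logical(nbins)
  for (b in seq_len(nbins)) {
    cols <- ((b - 1L) * nwin + 1L):(b * nwin)
    ok <- cols[!badWin[cols]]
    valid[b] <- maskedFraction[b] <= 0.5 && length(ok) > 0
    if (length(ok) == 1L) power[b, ] <- psd[, ok]
    else if (length(ok) > 1L)
      power[b, ] <- apply(psd[, ok, drop = FALSE], 1, stats::median)
  }
  structure(list(time = (seq_len(nbins) - 1) * binSec,
                 freq = freqAll[keep], power = power, valid = valid,
                 maskedFraction = maskedFraction, binSec = binSec,
                 df = samplingRate / wlen),
            class = "SpectralFrames")
}

#' @export
print.SpectralFrames <- function(x, ...) {
  cat(sprintf("SpectralFrames: %d bins of %g s, %d frequencies (%g-%g Hz), %d invalid\n",
              length(x$time), x$binSec, length(x$freq), min(x$freq),
              max(x$freq), sum(!x$valid)))
  invisible(x)
}

## Integrate frame power density over each band (power in mV^2).
frameBandPower <- function(frames, bands) {
  lab <- bandOfFrequency(frames$freq, bands)
  out <- vapply(bands$band, function(b) {
    cols <- which(lab == b)
    rowSums(frames$power[, cols, drop = FALSE]) * frames$df
  }, numeric(nrow(frames$power)))
  colnames(out) <- bands$band
  out
}

#' Minute-level band power
#'
#' Integrates each valid frame's median power density over the frequency
#' bands and averages frames within each minute (6 frames/min nominal).
#' Minutes with no valid frame are flagged missing. Because the bands
#' tile the analysis range, the per-band powers sum to the total
#' 0.5-80 Hz power exactly.
#'
#' @param frames a [spectrogramMedianBins()] result.
#' @param bands band table from [defaultBands()].
#' @param activity optional per-minute activity counts to attach.
#' @return data.frame with `minute` (0-based), one raw-power column per
#'   band (mV^2), `total`, `nFrames`, `missing`, and `activity` if given.
#' @export
minuteBandPower <- function(frames, bands = defaultBands(), activity = NULL) {
  checkBandTiling(bands, min(bands$low), max(bands$high))
  bp <- frameBandPower(frames, bands)
  minute <- frames$time %/% 60
  minutes <- sort(unique(minute))
  agg <- function(v) tapply(ifelse(frames$valid, v, NA), minute,
                            function(z) mean(z, na.rm = TRUE))
  out <- data.frame(minute = minutes)
  for (b in bands$band) out[[b]] <- as.numeric(agg(bp[, b]))
  out$total <- rowSums(out[, bands$band, drop = FALSE])
  out$nFrames <- as.integer(tapply(frames$valid, minute, sum))
  out$missing <- out$nFrames == 0
  out$total[out$missing] <- NA_real_
  if (!is.null(activity))
    out$activity <- activity[out$minute + 1L]
  out
}

#' Tenth-percentile normalization of minute power
#'
#' Divides every band and the total power by the 10th percentile (linear
#' interpolation between order statistics) of the subject's per-minute
#' TOTAL power, putting subjects on a common scale: after normalization
#' the 10th percentile of total power is exactly 1, and the result is
#' invariant under rescaling of the raw trace.
#'
#' @param mp a [minuteBandPower()] table.
#' @param bands band table (for the column names).
#' @return `mp` with added `<band>_norm` and `total_norm` columns and an
#'   attribute `p10` (the divisor, mV^2).
#' @export
normalizeToTenthPercentile <- function(mp, bands = defaultBands()) {
  tot <- mp$total[!mp$missing]
  if (length(tot) < 10)
    stop("need at least 10 non-missing minutes to take a 10th percentile")
  p10 <- unname(stats::quantile(tot, 0.10, type = 7))
  if (p10 <= 0) stop("degenerate recording: 10th percentile of total power is 0")
  for (b in c(bands$band, "total"))
    mp[[paste0(b, "_norm")]] <- mp[[b]] / p10
  attr(mp, "p10") <- p10
  mp
}

#' Hourly (zeitgeber-time) profile of normalized power
#'
#' Assigns minutes to clock hours, converts to hours relative to light
#' onset (ZT0 = lights on), and averages the normalized band and total
#' power per ZT hour across days.
#'
#' @param mp a normalized minute table from [normalizeToTenthPercentile()].
#' @param startClockHour clock hour of the first minute.
#' @param lightOnsetHour clock hour of light onset.
#' @param bands band table.
#' @return data.frame with `zt` (0-23), one `<band>_norm` mean per band,
#'   `total_norm`, and `nMinutes`.
#' @export
hourlyProfile <- function(mp, startClockHour = 6, lightOnsetHour = 6,
                          bands = defaultBands()) {
  if (nrow(mp) < 1440) stop("need at least 24 h of minutes for an hourly profile")
  clockHour <- (startClockHour + mp$minute / 60) %% 24
  zt <- floor((clockHour - lightOnsetHour) %% 24)
  cols <- paste0(c(bands$band, "total"), "_norm")
  ok <- !mp$missing
  out <- data.frame(zt = 0:23)
  for (cc in cols)
    out[[cc]] <- as.numeric(tapply(mp[[cc]][ok], zt[ok], mean))[
      match(out$zt, sort(unique(zt[ok])))]
  out$nMinutes <- as.integer(table(factor(zt[ok], levels = 0:23)))
  out
}

#' Percent of total power per band
#'
#' Per minute, each band's share of total power in percent (the shares
#' sum to 100 by construction since the bands tile the range), averaged
#' over all non-missing minutes.
#'
#' @param mp a [minuteBandPower()] table.
#' @param bands band table.
#' @return list with `minutes` (per-minute percentage data.frame) and
#'   `average` (named vector of recording-average percentages).
#' @export
percentTotalPower <- function(mp, bands = defaultBands()) {
  ok <- !mp$missing
  if (!any(ok)) stop("no non-missing minutes")
  pm <- data.frame(minute = mp$minute[ok])
  for (b in bands$band) pm[[b]] <- 100 * mp[[b]][ok] / mp$total[ok]
  avg <- colMeans(pm[, bands$band, drop = FALSE])
  list(minutes = pm, average = avg)
}

#' Per-band linear regression of raw power on activity
#'
#' Ordinary least squares of per-minute RAW band power on the minute's
#' activity count, one fit per band. This is the relationship used both
#' for reporting and for the delta-slope quality-control rule
#' (normalization is applied only to the time-based analyses).
#'
#' @param mp a [minuteBandPower()] table with an `activity` column.
#' @param bands band table.
#' @return data.frame with `band`, `slope`, `intercept`, `r2`, `se`
#'   (slope standard error), `n`.
#' @export
bandActivityRegression <- function(mp, bands = defaultBands()) {
  ok <- !mp$missing & !is.na(mp$activity)
  if (length(unique(mp$activity[ok])) < 2)
    stop("regression undefined: fewer than 2 distinct activity values")
  out <- lapply(bands$band, function(b) {
    fit <- stats::lm(mp[[b]][ok] ~ mp$activity[ok])
    sm <- suppressWarnings(summary(fit))   # exact fits are legitimate here
    data.frame(band = b,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r2 = sm$r.squared,
               se = sm$coefficients[2, 2],
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean band power per activity level
#'
#' Maps per-minute activity counts to integer levels 0-10 (counts of 10
#' or more pooled at 10) and returns the per-level mean raw power per
#' band, mirroring the activity-state analysis of band power.
#'
#' @param mp a [minuteBandPower()] table with `activity`.
#' @param bands band table.
#' @param nLevels number of levels (default 11: 0-10).
#' @return data.frame with `level` and one mean-power column per band.
#' @export
activityBinnedPower <- function(mp, bands = defaultBands(), nLevels = 11) {
  ok <- !mp$missing & !is.na(mp$activity)
  if (!any(ok)) stop("no usable minutes")
  cap <- nLevels - 1
  lev <- pmin(floor(mp$activity[ok]), cap)
  out <- data.frame(level = sort(unique(lev)))
  for (b in bands$band)
    out[[b]] <- as.numeric(tapply(mp[[b]][ok], lev, mean))
  out
}

#' Delta-vs-activity quality-control rule
#'
#' Delta power should decrease with locomotor activity in an
#' interpretable recording; a positive delta-on-activity slope indicates
#' movement-induced noise and excludes the subject.
#'
#' @param reg a [bandActivityRegression()] table.
#' @return list with `deltaSlope`, `excluded` (TRUE iff the slope is
#'   positive) and `reason`.
#' @export
qcDeltaActivity <- function(reg) {
  row <- reg[reg$band == "delta", ]
  if (nrow(row) != 1) stop("delta regression not found")
  excluded <- row$slope > 0
  list(deltaSlope = row$slope, excluded = excluded,
       reason = if (excluded) "delta power increases with activity" else NA_character_)
}

#' Subject-level quality-control report
#'
#' A subject is excluded when delta power increases with activity or when
#' at least 5\% of scored epochs are artifact.
#'
#' @param subjectId subject label.
#' @param deltaSlope delta-on-activity OLS slope (raw power units/count).
#' @param artifactFraction fraction of artifact epochs in the scored day.
#' @return data.frame with one row: `subjectId`, `deltaSlope`,
#'   `artifactFraction`, `excluded`, `reason`.
#' @export
qcReport <- function(subjectId, deltaSlope, artifactFraction) {
  reasons <- c(
    if (deltaSlope > 0) "delta power increases with activity",
    if (artifactFraction >= 0.05) ">=5% artifact epochs")
  data.frame(subjectId = subjectId, deltaSlope = deltaSlope,
             artifactFraction = artifactFraction,
             excluded = length(reasons) > 0,
             reason = if (length(reasons)) paste(reasons, collapse = "; ")
                      else NA_character_,
             stringsAsFactors = FALSE)
}
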
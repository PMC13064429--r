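#' Per-epoch staging features
#'
#' Computes, for each 10 s epoch (one spectrogram bin), the feature
#' vector the staging rule operates on: the delta fraction of EEG power
#' (slow-wave activity), the theta/delta ratio (medium-wave activity),
#' the EMG RMS z-scored against the recording's quiet floor, the epoch's
#' activity count, and the fraction of artifact-masked samples.
#'
#' Activity counts exist per minute only; each minute's count is
#' apportioned to its six epochs by largest-remainder allocation weighted
#' by epoch EMG RMS, since movement and EMG tone co-occur. A minute with
#' zero counts contributes zero to all of its epochs. The EMG floor is
#' the median RMS over the quieter half of epochs, scaled by their MAD,
#' so wake epochs score large positive z values and atonic epochs score
#' at or below zero.
#'
#' @param frames a [spectrogramMedianBins()] result on the spectral
#'   branch (0.5 Hz high-passed) EEG.
#' @param emgTrace raw EMG trace (mV).
#' @param activityCounts per-minute activity counts.
#' @param samplingRate sampling rate (Hz).
#' @param bands band table.
#' @return data.frame with `epoch` (1-based), `deltaFrac`, `thetaDelta`,
#'   `emgZ`, `activity`, `artifactFrac`, `valid`.
#' @export
epochFeatures <- function(frames, emgTrace, activityCounts, samplingRate,
                          bands = defaultBands()) {
  nE <- length(frames$time)
  bp <- frameBandPower(frames, bands)
  total <- rowSums(bp)
  deltaFrac <- bp[, "delta"] / total
  thetaDelta <- bp[, "theta"] / bp[, "delta"]

  epochLen <- frames$binSec * samplingRate
  used <- nE * epochLen
  rms <- sqrt(colMeans(matrix(emgTrace[seq_len(used)]^2, nrow = epochLen)))

  quiet <- rms <= stats::median(rms)
  mu <- stats::median(rms[quiet])
  s <- stats::mad(rms[quiet])
  s <- max(s, 0.05 * mu, .Machine$double.eps)
  emgZ <- (rms - mu) / s

  activity <- apportionActivity(activityCounts, rms, nE)

  data.frame(epoch = seq_len(nE), deltaFrac = deltaFrac,
             thetaDelta = thetaDelta, emgZ = emgZ, activity = activity,
             artifactFrac = frames$maskedFraction, valid = frames$valid)
}

## Largest-remainder apportionment of per-minute counts to epochs,
## weighted by epoch EMG RMS.
apportionActivity <- function(activityCounts, rms, nE) {
  out <- numeric(nE)
  for (m in seq_along(activityCounts)) {
    idx <- ((m - 1L) * 6L + 1L):min(m * 6L, nE)
    if (idx[1] > nE) break
    cnt <- activityCounts[m]
    if (is.na(cnt) || cnt <= 0) next
    w <- rms[idx]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(idx), length(idx))
    exact <- cnt * w
    base <- floor(exact)
    left <- round(cnt - sum(base))
    if (left > 0) {
      extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
      base[extra] <- base[extra] + 1
    }
    out[idx] <- base
  }
  out
}

#' Default staging thresholds
#'
#' @return named list: `deltaMin` (minimum delta fraction for NREM),
#'   `thetaDeltaMin` (minimum theta/delta ratio for REM), `zWake` (EMG z
#'   at or above which an epoch is wake), `zSleep` (EMG z at or below
#'   which sleep is admissible), `artifactSleep` and `artifactWake`
#'   (artifact-fraction cutoffs for sleep-candidate and wake-candidate
#'   epochs; only large artifacts mark wake epochs as artifact).
#' @export
stagingThresholds <- function() {
  list(deltaMin = 0.4, thetaDeltaMin = 1.5, zWake = 1.0, zSleep = 0.5,
       artifactSleep = 0.5, artifactWake = 0.8)
}

#' Rule-based staging of 10 s epochs
#'
#' Deterministic surrogate for manual scoring, applied in fixed order per
#' epoch: an epoch is wake when there is a signal in the activity channel
#' or a distinct EMG signal; NREM when activity is absent, slow-wave
#' (delta) activity dominates and EMG is minimal; REM when activity is
#' absent, the theta/delta ratio is high and EMG is minimal. An epoch
#' whose artifact fraction reaches the cutoff (0.5 for sleep candidates;
#' 0.8 for wake candidates, since only large artifacts in wake are scored
#' as artifact) is labeled artifact. When no rule fires the previous
#' epoch's stage carries over (wake for the first epoch).
#'
#' @param features an [epochFeatures()] table.
#' @param thresholds see [stagingThresholds()].
#' @return character vector of stages
#'   (`"wake"`, `"NREM"`, `"REM"`, `"artifact"`), one per epoch.
#' @export
scoreEpochs <- function(features, thresholds = stagingThresholds()) {
  th <- thresholds
  n <- nrow(features)
  stages <- character(n)
  prev <- "wake"
  for (i in seq_len(n)) {
    f <- features[i, ]
    wakeCand <- (!is.na(f$activity) && f$activity > 0) || f$emgZ >= th$zWake
    cut <- if (wakeCand) th$artifactWake else th$artifactSleep
    st <- if (f$artifactFrac >= cut) "artifact"
      else if (wakeCand) "wake"
      else if (!is.na(f$deltaFrac) && f$deltaFrac >= th$deltaMin &&
               f$emgZ <= th$zSleep) "NREM"
      else if (!is.na(f$thetaDelta) && f$thetaDelta >= th$thetaDeltaMin &&
               f$emgZ <= th$zSleep) "REM"
      else prev
    stages[i] <- st
    if (st != "artifact") prev <- st
  }
  stages
}

#' Majority rule for sub-epoch labels
#'
#' An epoch containing more than one stage is scored as the stage that
#' occupies most of it; ties break by the precedence
#' artifact > wake > NREM > REM (the order of the staging rule).
#'
#' @param labels character vector of sub-epoch stage labels.
#' @return The modal stage label.
#' @export
majorityStage <- function(labels) {
  stopifnot(length(labels) >= 1)
  prec <- c("artifact", "wake", "NREM", "REM")
  counts <- table(factor(labels, levels = prec))
  names(counts)[which.max(counts)]   # which.max takes the first = highest precedence
}

#' Artifact-based recording exclusion
#'
#' Recordings in which at least 5\% of scored epochs are artifact are
#' excluded from analysis (the bound is inclusive: exactly 5\% excludes).
#'
#' @param stages character vector of epoch stages.
#' @param threshold exclusion bound on the artifact fraction.
#' @return list with `artifactFraction` and `excluded`.
#' @export
artifactExclusion <- function(stages, threshold = 0.05) {
  frac <- mean(stages == "artifact")
  list(artifactFraction = frac, excluded = frac >= threshold)
}

#' Sleep summary: stage percentages, bouts, per-stage spectra
#'
#' Percent time per stage for the lights-on period (day), lights-off
#' period (night) and the full cycle; sleep bouts (maximal runs of
#' consecutive NREM/REM epochs of at least `minBoutEpochs`) with count
#' and mean duration; and the mean power spectrum over each stage's valid
#' frames.
#'
#' @param stages character vector of epoch stages.
#' @param startClockHour clock hour of the first epoch.
#' @param lightOnsetHour,lightOffsetHour light schedule (clock hours).
#' @param frames optional [spectrogramMedianBins()] result aligned with
#'   `stages`, for per-stage spectra.
#' @param minBoutEpochs minimum sleep-bout length in epochs (default 3,
#'   i.e. 30 s).
#' @param epochSec epoch length (s).
#' @return list with `percent` (data.frame stage x day/night/cycle),
#'   `boutCount`, `meanBoutMinutes`, and `stageSpectra` (stage x
#'   frequency matrix, or `NULL`).
#' @export
sleepSummary <- function(stages, startClockHour = 6, lightOnsetHour = 6,
                         lightOffsetHour = 18, frames = NULL,
                         minBoutEpochs = 3, epochSec = 10) {
  n <- length(stages)
  clock <- (startClockHour + (seq_len(n) - 1) * epochSec / 3600) %% 24
  isDay <- inLightPhase(clock, lightOnsetHour, lightOffsetHour)
  lev <- c("wake", "NREM", "REM", "artifact")
  pct <- function(sel) 100 * as.numeric(table(factor(stages[sel], levels = lev))) /
    max(1, sum(sel))
  percent <- data.frame(stage = lev,
                        day = pct(isDay), night = pct(!isDay),
                        cycle = pct(rep(TRUE, n)))

  sleep <- stages %in% c("NREM", "REM")
  r <- rle(sleep)
  boutLens <- r$lengths[r$values & r$lengths >= minBoutEpochs]
  boutCount <- length(boutLens)
  meanBoutMinutes <- if (boutCount) mean(boutLens) * epochSec / 60 else 0

  stageSpectra <- NULL
  if (!is.null(frames)) {
    stopifnot(length(frames$time) >= n)
    stageSpectra <- t(vapply(lev, function(s) {
      sel <- which(stages == s & frames$valid[seq_len(n)])
      if (!length(sel)) return(rep(NA_real_, length(frames$freq)))
      colMeans(frames$power[sel, , drop = FALSE])
    }, numeric(length(frames$freq))))
    colnames(stageSpectra) <- frames$freq
  }
  list(percent = percent, boutCount = boutCount,
       meanBoutMinutes = meanBoutMinutes, stageSpectra = stageSpectra)
}
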
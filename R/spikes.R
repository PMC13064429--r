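#' Robust baseline SD of the filtered EEG
#'
#' The spike threshold is expressed in multiples of the SD of baseline
#' EEG. Baseline is estimated robustly as the scaled median absolute
#' deviation over all unmasked samples of the 6.3 Hz high-passed trace,
#' which is insensitive to sparse spikes.
#'
#' @param x filtered EEG trace (mV).
#' @param mask optional logical artifact mask.
#' @param samplingRate sampling rate (Hz); at least one minute of
#'   unmasked data is required.
#' @return baseline SD (mV), strictly positive.
#' @export
estimateBaselineSd <- function(x, mask = NULL, samplingRate = 500) {
  if (!is.null(mask)) x <- x[!mask]
  if (length(x) < 60 * samplingRate)
    stop("need at least one minute of unmasked data to estimate baseline SD")
  s <- stats::mad(x)
  if (!is.finite(s) || s <= 0)
    stop("degenerate trace: baseline SD is zero")
  s
}

#' Threshold-based spike candidate detection
#'
#' Flags every sample whose absolute filtered voltage reaches
#' `k` times the baseline SD, merges flagged runs separated by no more
#' than a 10 ms refractory gap into single candidates, and measures each
#' candidate's peak time, peak amplitude (in SD units), threshold-crossing
#' width, and half-decay time (peak to half-peak). Masked (artifact)
#' samples never trigger detection. Raising `k` can only shrink the
#' candidate set.
#'
#' @param x 6.3 Hz high-passed EEG trace (mV).
#' @param samplingRate sampling rate (Hz).
#' @param sd baseline SD (mV), see [estimateBaselineSd()].
#' @param k detection threshold in SD units (default 10).
#' @param gapMs refractory merge gap (ms).
#' @param mask optional logical artifact mask.
#' @return data.frame with `time` (s, peak), `amplitude` (peak/SD),
#'   `widthMs`, `halfDecayMs`, `start`, `end` (s). Zero rows when nothing
#'   crosses threshold.
#' @export
detectSpikes <- function(x, samplingRate, sd, k = 10, gapMs = 10, mask = NULL) {
  stopifnot(sd > 0, k > 0)
  thr <- k * sd
  above <- abs(x) >= thr
  if (!is.null(mask)) above <- above & !mask
  empty <- data.frame(time = numeric(0), amplitude = numeric(0),
                      widthMs = numeric(0), halfDecayMs = numeric(0),
                      start = numeric(0), end = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runS <- starts[r$values]
  runE <- ends[r$values]
  ## merge runs separated by <= gap samples
  gap <- round(gapMs / 1000 * samplingRate)
  if (length(runS) > 1) {
    newGroup <- c(TRUE, runS[-1] - runE[-length(runE)] - 1L > gap)
    grp <- cumsum(newGroup)
    runS <- tapply(runS, grp, min)
    runE <- tapply(runE, grp, max)
  }
  n <- length(x)
  out <- lapply(seq_along(runS), function(i) {
    i0 <- runS[[i]]; i1 <- runE[[i]]
    seg <- abs(x[i0:i1])
    pk <- i0 + which.max(seg) - 1L
    peakAbs <- abs(x[pk])
    ## half-decay: time until the deflection has decayed to half the
    ## peak, taken as the LAST time (within 150 ms) the 5-sample running
    ## median of the same-sign deflection sits at or above half-peak, so
    ## neither a noisy dip right after the peak nor a single outlying
    ## sample distorts it, and opposite-sign undershoot is ignored
    lim <- min(pk + round(0.15 * samplingRate), n)
    post <- x[pk:lim] * sign(x[pk])
    if (length(post) >= 5) post <- stats::runmed(post, 5)
    aboveHalf <- which(post >= peakAbs / 2)
    data.frame(time = (pk - 1) / samplingRate,
               amplitude = peakAbs / sd,
               widthMs = (i1 - i0 + 1) / samplingRate * 1000,
               halfDecayMs = if (length(aboveHalf))
                 max(aboveHalf) / samplingRate * 1000
               else 0,
               start = (i0 - 1) / samplingRate,
               end = i1 / samplingRate)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Waveform-duration filter
#'
#' Retains only candidates whose threshold-crossing width lies in the
#' admissible waveform range (15-70 ms by default); shorter events are
#' noise clicks, longer ones slow artifacts.
#'
#' @param events a [detectSpikes()] table.
#' @param minMs,maxMs admissible width range (ms).
#' @return The filtered event table.
#' @export
filterByWidth <- function(events, minMs = 15, maxMs = 70) {
  events[events$widthMs >= minMs & events$widthMs <= maxMs, , drop = FALSE]
}

#' Morphological spike classification
#'
#' Assigns each retained event to one of three classes on (amplitude in
#' SD units, half-decay time): class A are high-amplitude, quick-bursting
#' spikes (`amplitude >= aA` and `halfDecayMs <= dFastMs`); class C are
#' low and slow signals that just passed the amplitude threshold
#' (`amplitude < aB` and `halfDecayMs >= dSlowMs`); everything else is
#' class B (lower-amplitude spikes with a slower return to baseline).
#' Every event receives exactly one class.
#'
#' @param events event table with `amplitude` and `halfDecayMs`.
#' @param aA,aB amplitude boundaries (SD units).
#' @param dFastMs,dSlowMs half-decay boundaries (ms).
#' @return `events` with an added `class` column.
#' @export
classifySpikes <- function(events, aA = 20, aB = 12,
                           dFastMs = 15, dSlowMs = 30) {
  cl <- rep("B", nrow(events))
  cl[events$amplitude >= aA & events$halfDecayMs <= dFastMs] <- "A"
  cl[events$amplitude < aB & events$halfDecayMs >= dSlowMs] <- "C"
  events$class <- cl
  events
}

#' Spikes-per-hour summary
#'
#' Per-class and total event counts divided by the unmasked analyzed
#' time; per-class rates sum to the total rate.
#'
#' @param events classified event table.
#' @param analyzedHours total hours analyzed.
#' @param maskedHours hours removed by the artifact mask.
#' @return data.frame with rates for classes A, B, C and `total`, plus
#'   `hoursAnalyzed`.
#' @export
spikeRate <- function(events, analyzedHours, maskedHours = 0) {
  denom <- analyzedHours - maskedHours
  if (denom <= 0) stop("no analyzable hours")
  counts <- table(factor(events$class, levels = c("A", "B", "C")))
  data.frame(A = counts[["A"]] / denom, B = counts[["B"]] / denom,
             C = counts[["C"]] / denom, total = nrow(events) / denom,
             hoursAnalyzed = denom)
}

#' Match detected events to ground-truth times
#'
#' Greedy one-to-one matching within a tolerance window, for scoring
#' detection against a simulation's ground truth.
#'
#' @param detected event table with `time` (and optionally `class`).
#' @param truth data.frame with `time` (and optionally `class`).
#' @param tolSec matching window (s), default 25 ms.
#' @return list with `recall`, `precision`, `nMatched`, and
#'   `classAgreement` (fraction of matched pairs with equal class, `NA`
#'   when classes are absent).
#' @export
matchSpikeEvents <- function(detected, truth, tolSec = 0.025) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nt == 0)
    return(list(recall = NA_real_, precision = if (nd) 0 else 1,
                nMatched = 0L, classAgreement = NA_real_))
  usedD <- logical(nd)
  matchOf <- integer(0)
  truthIdx <- integer(0)
  for (i in order(truth$time)) {
    if (nd == 0) break
    dt <- abs(detected$time - truth$time[i])
    dt[usedD] <- Inf
    j <- which.min(dt)
    if (is.finite(dt[j]) && dt[j] <= tolSec) {
      usedD[j] <- TRUE
      matchOf <- c(matchOf, j)
      truthIdx <- c(truthIdx, i)
    }
  }
  m <- length(matchOf)
  agree <- NA_real_
  if (m > 0 && !is.null(detected$class) && !is.null(truth$class))
    agree <- mean(detected$class[matchOf] == truth$class[truthIdx])
  list(recall = m / nt, precision = if (nd) m / nd else NA_real_,
       nMatched = m, classAgreement = agree)
}
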
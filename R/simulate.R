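## Synthetic telemetry generator: 1/f background EEG with state-dependent
## band oscillations, a hidden semi-Markov wake/NREM/REM sequence,
## EMG tone tied to state, circadian-modulated activity counts, injected
## spike waveforms of three morphologies, and injected artifacts.
## Everything downstream is tested against the ground truth this emits.

simStates <- c("wake", "NREM", "REM")

#' Default state-by-band oscillation amplitudes (mV)
#'
#' Wake carries theta plus broadband/gamma activity, NREM is delta
#' (slow-wave) dominated, REM is theta dominated. Each enabled entry adds
#' a sinusoid of that amplitude at the band's carrier frequency, so the
#' expected oscillatory band power is amplitude^2 / 2.
#'
#' @return 3 x 5 matrix, rows `wake`/`NREM`/`REM`, columns the bands.
#' @export
defaultStateAmplitudes <- function() {
  m <- matrix(0, 3, 5, dimnames = list(simStates,
                c("delta", "theta", "alpha", "beta", "gamma")))
  m["wake", "theta"] <- 0.04
  m["wake", "gamma"] <- 0.06
  m["NREM", "delta"] <- 0.20
  m["REM", "theta"] <- 0.15
  m
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic telemetry generator with
#' defaults emulating a standard mouse wireless-telemetry study: 500 Hz
#' sampling, 12 h light/dark cycle with lights on at 6 h, pink (1/f)
#' background EEG, and a semi-Markov sleep-state schedule with longer
#' wake bouts in the dark phase.
#'
#' @param durationHours recording length (h); at least 10 min, rounded to
#'   whole 10 s epochs.
#' @param samplingRate sampling rate (Hz); must exceed 160 Hz so the
#'   80 Hz band edge is representable, and twice the fastest carrier.
#' @param startClockHour clock hour of the first sample.
#' @param lightOnsetHour,lightOffsetHour light schedule (clock hours).
#' @param backgroundExponent exponent alpha of the 1/f^alpha background.
#' @param backgroundSd total SD of the background (mV).
#' @param stateBandAmplitudes state x band sinusoid amplitudes (mV), see
#'   [defaultStateAmplitudes()].
#' @param oscFrequencies carrier frequency per band (Hz); the defaults sit
#'   on the 2 Hz grid of the 500 ms analysis window inside each band.
#' @param emgStateSd EMG noise SD per state (mV); wake high, REM atonia.
#' @param activityRate expected activity counts/min during full wake, by
#'   light phase; sleep minutes emit zero.
#' @param spikeRates injected epileptiform events per hour per class.
#' @param spikeAmplitudes peak amplitude per class, in multiples of the
#'   unit SD (the robust SD of the 6.3 Hz high-passed spike-free trace).
#' @param artifactRate injected artifact events per hour.
#' @param artifactAmplitudeMv artifact excursion amplitude (> 2 mV).
#' @param artifactDurationSec duration of each artifact (s).
#' @param dwellEpochs mean bout length, in 10 s epochs, for
#'   `wakeLight`, `wakeDark`, `NREM`, `REM`.
#' @param pRemEntry probability that a NREM bout is followed by REM
#'   (REM is entered only from NREM).
#' @param pRemToWake probability that a REM bout ends in wake.
#' @param fixedState optional single state (`"wake"`, `"NREM"`, `"REM"`)
#'   to hold throughout, for single-state calibration experiments.
#' @param rngSeed integer seed; identical configs give bit-identical
#'   recordings.
#' @return A validated list of class `"SimConfig"`.
#' @examples
#' cfg <- simConfig(durationHours = 1, rngSeed = 7)
#' names(cfg)[1:6]
#' @export
simConfig <- function(durationHours = 24,
                      samplingRate = 500,
                      startClockHour = 6,
                      lightOnsetHour = 6,
                      lightOffsetHour = 18,
                      backgroundExponent = 1,
                      backgroundSd = 0.05,
                      stateBandAmplitudes = defaultStateAmplitudes(),
                      oscFrequencies = c(delta = 2, theta = 6, alpha = 10,
                                         beta = 20, gamma = 40),
                      emgStateSd = c(wake = 0.10, NREM = 0.02, REM = 0.01),
                      activityRate = c(light = 3, dark = 5),
                      spikeRates = c(A = 0, B = 0, C = 0),
                      spikeAmplitudes = c(A = 22, B = 15, C = 11.5),
                      artifactRate = 0,
                      artifactAmplitudeMv = 3,
                      artifactDurationSec = 1,
                      dwellEpochs = c(wakeLight = 15, wakeDark = 54,
                                      NREM = 12, REM = 8),
                      pRemEntry = 0.5,
                      pRemToWake = 0.8,
                      fixedState = NULL,
                      rngSeed = 1L) {
  cfg <- structure(as.list(environment()), class = "SimConfig")
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  if (cfg$durationHours * 3600 < 600)
    stop("duration below 10 min: too short for one staging cycle")
  if (cfg$samplingRate <= 160)
    stop("sampling rate must exceed 160 Hz to represent the 80 Hz band edge")
  if (cfg$samplingRate <= 2 * max(cfg$oscFrequencies))
    stop("sampling rate must exceed twice the highest carrier frequency")
  if (cfg$artifactAmplitudeMv <= 2)
    stop("artifact amplitude must exceed 2 mV")
  rates <- c(cfg$spikeRates, cfg$artifactRate, cfg$activityRate)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (!all(rownames(cfg$stateBandAmplitudes) == simStates))
    stop("stateBandAmplitudes rows must be wake, NREM, REM")
  invisible(cfg)
}

## Evaluate `code` under a fixed seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

## Gaussian 1/f^(alpha) noise via FFT spectral shaping; the spectrum is
## flattened below fFloor so the trace has no runaway drift. Long traces
## are synthesized in segments of at most maxSeg samples (several hours
## at 500 Hz) to bound the FFT working memory; segments are independent,
## which only forfeits spectral coherence at periods longer than a
## segment, far below fFloor.
pinkNoise <- function(n, alpha = 1, sd = 1, samplingRate = 500, fFloor = 0.5,
                      maxSeg = 2^23) {
  one <- function(nn) {
    m <- stats::nextn(nn, c(2, 3, 5))
    half <- m %/% 2
    f <- seq_len(half - 1) * samplingRate / m
    shape <- pmax(f, fFloor)^(-alpha / 2)
    z <- complex(real = stats::rnorm(half - 1),
                 imaginary = stats::rnorm(half - 1)) * shape
    spec <- c(0, z, stats::rnorm(1) * (samplingRate / 2)^(-alpha / 2),
              Conj(rev(z)))
    rm(z, shape, f)
    x <- stats::fft(spec, inverse = TRUE)
    rm(spec)
    Re(x)[seq_len(nn)]
  }
  if (n <= maxSeg) {
    x <- one(n)
  } else {
    nseg <- ceiling(n / maxSeg)
    len <- ceiling(n / nseg)
    x <- numeric(n)
    pos <- 1L
    while (pos <= n) {
      k <- min(len, n - pos + 1L)
      x[pos:(pos + k - 1L)] <- one(k)
      pos <- pos + k
      gc(FALSE)
    }
  }
  gc(FALSE)
  x * (sd / stats::sd(x))
}

## Semi-Markov hidden state sequence over 10 s epochs. REM is entered
## only from NREM; wake bouts are longer in the dark phase.
makeStateSequence <- function(nEpochs, lightByEpoch, dwellEpochs,
                              pRemEntry, pRemToWake) {
  states <- character(nEpochs)
  pos <- 1L
  cur <- "wake"
  while (pos <= nEpochs) {
    mean <- switch(cur,
      wake = if (lightByEpoch[pos]) dwellEpochs[["wakeLight"]]
             else dwellEpochs[["wakeDark"]],
      NREM = dwellEpochs[["NREM"]],
      REM = dwellEpochs[["REM"]])
    dwell <- 1L + stats::rgeom(1, 1 / mean)
    end <- min(pos + dwell - 1L, nEpochs)
    states[pos:end] <- cur
    pos <- end + 1L
    cur <- switch(cur,
      wake = "NREM",
      NREM = if (stats::runif(1) < pRemEntry) "REM" else "wake",
      REM = if (stats::runif(1) < pRemToWake) "wake" else "NREM")
  }
  states
}

## Ideal (pre-filter) spike shapes: half-cosine rise, optional plateau,
## half-cosine fall; durations in ms chosen so the 10 x SD threshold
## crossing width and the half-decay time land in each class's range.
spikeShapeParams <- function(classLabel) {
  switch(classLabel,
    A = list(riseMs = 12, plateauMs = 0, fallMs = 17),
    B = list(riseMs = 12, plateauMs = 0, fallMs = 42),
    C = list(riseMs = 10, plateauMs = 20, fallMs = 36),
    stop("unknown spike class '", classLabel, "' (expected A, B or C)"))
}

risePlateauFall <- function(riseMs, plateauMs, fallMs, samplingRate) {
  nR <- round(riseMs / 1000 * samplingRate)
  nP <- round(plateauMs / 1000 * samplingRate)
  nF <- round(fallMs / 1000 * samplingRate)
  c(sin(seq_len(nR) / nR * pi / 2), rep(1, nP),
    cos(seq_len(nF) / nF * pi / 2))
}

#' Generate an epileptiform spike template
#'
#' Builds the class's idealized transient (class A: high-amplitude fast
#' spike; B: lower amplitude with slower return to baseline; C: low, slow
#' signal that just clears the amplitude threshold), passes it through the
#' same 6.3 Hz zero-phase high-pass used by the detection branch, and
#' rescales the result so its peak equals `amplitude * unitSd`. Because
#' the template is already band-limited, detection-stage filtering leaves
#' its morphology (threshold-crossing width, half-decay) essentially
#' unchanged, so ground-truth morphology equals detected morphology.
#'
#' @param classLabel `"A"`, `"B"` or `"C"`.
#' @param samplingRate sampling rate (Hz).
#' @param amplitude peak amplitude in multiples of `unitSd`; defaults to
#'   the class defaults of [simConfig()] (A 22, B 15, C 11.5).
#' @param unitSd the baseline SD (mV) the amplitude is expressed in.
#' @param hpCoef optional precomputed 6.3 Hz filter coefficients.
#' @return numeric waveform (mV) with attributes `peakIndex`,
#'   `spikeClass` and `nominalWidthMs` (the duration of the generating
#'   transient, 15-70 ms: class A 29 ms, B 54 ms, C 66 ms).
#' @examples
#' tpl <- makeSpikeTemplate("A", 500)
#' max(abs(tpl))  # 22 unit SDs
#' @export
makeSpikeTemplate <- function(classLabel, samplingRate,
                              amplitude = NULL, unitSd = 1,
                              hpCoef = NULL) {
  p <- spikeShapeParams(classLabel)
  if (is.null(amplitude))
    amplitude <- c(A = 22, B = 15, C = 11.5)[[classLabel]]
  d <- risePlateauFall(p$riseMs, p$plateauMs, p$fallMs, samplingRate)
  pad <- round(0.4 * samplingRate)
  if (is.null(hpCoef)) hpCoef <- designFirHighpass(6.3, samplingRate)
  v <- firApply(hpCoef, c(numeric(pad), d, numeric(pad)))
  v <- v * (amplitude * unitSd / max(abs(v)))
  structure(v, peakIndex = which.max(abs(v)), class = NULL,
            spikeClass = classLabel,
            nominalWidthMs = p$riseMs + p$plateauMs + p$fallMs)
}

#' Generate a width-decoy waveform
#'
#' Decoys are transients whose waveform duration falls outside the
#' 15-70 ms window and must therefore never survive the spike pipeline.
#' The `"short"` decoy (10 ms) is band-limited like a spike template, so
#' it is detected and then rejected by the width filter; the `"long"`
#' decoy (~100 ms and slower) is a sub-6.3 Hz hump that the spike-branch
#' high-pass suppresses below the detection threshold.
#'
#' @param type `"short"` or `"long"`.
#' @inheritParams makeSpikeTemplate
#' @return numeric waveform with attribute `peakIndex`.
#' @export
makeDecoyTemplate <- function(type = c("short", "long"), samplingRate,
                              unitSd = 1, hpCoef = NULL) {
  type <- match.arg(type)
  if (type == "short") {
    d <- risePlateauFall(5, 0, 5, samplingRate)
    pad <- round(0.4 * samplingRate)
    if (is.null(hpCoef)) hpCoef <- designFirHighpass(6.3, samplingRate)
    v <- firApply(hpCoef, c(numeric(pad), d, numeric(pad)))
    v <- v * (15 * unitSd / max(abs(v)))
  } else {
    v <- risePlateauFall(130, 60, 130, samplingRate) * 13 * unitSd
  }
  structure(v, peakIndex = which.max(abs(v)))
}

#' Add a waveform to a trace at given times
#'
#' @param x numeric trace.
#' @param template waveform with a `peakIndex` attribute (see
#'   [makeSpikeTemplate()]).
#' @param timesSec times (s) at which the template peak is placed.
#' @param samplingRate sampling rate (Hz).
#' @return The trace with the waveform added (edges clipped if needed).
#' @export
injectWaveform <- function(x, template, timesSec, samplingRate) {
  pk <- attr(template, "peakIndex")
  nt <- length(template)
  n <- length(x)
  for (tt in timesSec) {
    i0 <- round(tt * samplingRate) + 1L - (pk - 1L)
    src <- seq_len(nt)
    dst <- i0 + src - 1L
    ok <- dst >= 1L & dst <= n
    x[dst[ok]] <- x[dst[ok]] + template[src[ok]]
  }
  x
}

## Measure a template's morphology with the detector's conventions:
## crossing width (contiguous |v| >= threshold around the peak, gaps up
## to 10 ms bridged), half-decay (peak to half-peak), and the waveform
## extent (full width at 10% of peak) -- the visible transient duration
## that the 15-70 ms waveform contract refers to.
templateMetrics <- function(template, samplingRate, thresholdMv) {
  a <- abs(template)
  pk <- which.max(a)
  lim <- min(pk + round(0.15 * samplingRate), length(a))
  signedPost <- template[pk:lim] * sign(template[pk])
  aboveHalf <- which(signedPost >= a[pk] / 2)
  ext <- which(a >= 0.1 * a[pk])
  gap <- round(0.010 * samplingRate)
  above <- a >= thresholdMv
  widthMs <- 0
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    rs <- starts[r$values]; re <- ends[r$values]
    if (length(rs) > 1) {
      grp <- cumsum(c(TRUE, rs[-1] - re[-length(re)] - 1L > gap))
      rs <- tapply(rs, grp, min); re <- tapply(re, grp, max)
    }
    i <- which(rs <= pk & re >= pk)
    if (length(i)) widthMs <- (re[[i[1]]] - rs[[i[1]]] + 1) / samplingRate * 1000
  }
  list(widthMs = widthMs,
       halfDecayMs = if (length(aboveHalf)) max(aboveHalf) / samplingRate * 1000
                     else 0,
       extentMs = diff(range(ext)) / samplingRate * 1000)
}

#' Simulate a telemetry recording with ground truth
#'
#' Composes a pink (1/f^alpha) background, state-dependent band sinusoids
#' driven by a hidden semi-Markov wake/NREM/REM sequence, EMG noise whose
#' variance follows the state, per-minute Poisson activity counts emitted
#' only from wake time (with a light/dark rate difference), Poisson-placed
#' spike waveforms of three morphologies, and saturating artifacts.
#' Identical configurations produce bit-identical output.
#'
#' Spike amplitudes are calibrated in the detection domain: the generator
#' measures the robust SD of the 6.3 Hz high-passed spike-free trace (the
#' "unit SD") and scales each template to its configured multiple of it.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `recording` (a
#'   [TelemetryRecording-class]) and `truth` (a
#'   [SimGroundTruth-class]).
#' @examples
#' sim <- simulateRecording(simConfig(durationHours = 1/3, rngSeed = 2))
#' sim$recording
#' @export
simulateRecording <- function(config) {
  validateSimConfig(config)
  fs <- config$samplingRate
  nEpochs <- round(config$durationHours * 360)
  n <- nEpochs * 10L * fs
  durationSec <- n / fs

  withLocalSeed(config$rngSeed, {
    epochClock <- (config$startClockHour + (seq_len(nEpochs) - 1) * 10 / 3600) %% 24
    lightByEpoch <- inLightPhase(epochClock, config$lightOnsetHour,
                                 config$lightOffsetHour)
    states <- if (!is.null(config$fixedState)) {
      stopifnot(config$fixedState %in% simStates)
      rep(config$fixedState, nEpochs)
    } else {
      makeStateSequence(nEpochs, lightByEpoch, config$dwellEpochs,
                        config$pRemEntry, config$pRemToWake)
    }
    stateIdx <- match(states, simStates)

    ## EEG: pink background + state-gated band sinusoids; EMG: white
    ## noise with state-dependent variance. Both are assembled epoch by
    ## epoch in place to keep the working set small.
    eegTrace <- pinkNoise(n, config$backgroundExponent, config$backgroundSd,
                          fs, fFloor = 0.5)
    emgTrace <- stats::rnorm(n)
    amps <- config$stateBandAmplitudes
    epochLen <- 10L * fs
    tEpoch <- (seq_len(epochLen) - 1) / fs
    for (e in seq_len(nEpochs)) {
      idx <- ((e - 1L) * epochLen + 1L):(e * epochLen)
      s <- stateIdx[e]
      t0 <- (e - 1L) * 10
      for (b in colnames(amps)) {
        a <- amps[s, b]
        if (a == 0) next
        eegTrace[idx] <- eegTrace[idx] +
          a * sin(2 * pi * config$oscFrequencies[[b]] * (t0 + tEpoch))
      }
      emgTrace[idx] <- emgTrace[idx] * config$emgStateSd[[simStates[s]]]
    }
    gc(FALSE)

    ## per-minute activity: Poisson, rate scaled by the minute's wake share
    nMin <- nEpochs %/% 6L + (nEpochs %% 6L > 0)
    minuteOfEpoch <- (seq_len(nEpochs) - 1L) %/% 6L + 1L
    wakeFrac <- tapply(states == "wake", minuteOfEpoch, mean)
    minClock <- (config$startClockHour + (seq_len(nMin) - 1) / 60) %% 24
    lam <- ifelse(inLightPhase(minClock, config$lightOnsetHour,
                               config$lightOffsetHour),
                  config$activityRate[["light"]],
                  config$activityRate[["dark"]])
    act <- stats::rpois(nMin, lam * as.numeric(wakeFrac))

    ## unit SD in the detection domain, measured before spike injection
    hpCoef <- designFirHighpass(6.3, fs)
    unitSd <- stats::mad(firApply(hpCoef, eegTrace))
    gc(FALSE)

    ## spikes: Poisson counts per class, uniform times
    spikes <- data.frame(time = numeric(0), class = character(0),
                         amplitude = numeric(0), stringsAsFactors = FALSE)
    for (cl in c("A", "B", "C")) {
      k <- stats::rpois(1, config$spikeRates[[cl]] * durationSec / 3600)
      if (k == 0) next
      times <- sort(stats::runif(k, 1, durationSec - 1))
      tpl <- makeSpikeTemplate(cl, fs, amplitude = config$spikeAmplitudes[[cl]],
                               unitSd = unitSd, hpCoef = hpCoef)
      eegTrace <- injectWaveform(eegTrace, tpl, times, fs)
      spikes <- rbind(spikes, data.frame(
        time = times, class = cl,
        amplitude = config$spikeAmplitudes[[cl]], stringsAsFactors = FALSE))
    }
    spikes <- spikes[order(spikes$time), , drop = FALSE]
    rownames(spikes) <- NULL

    ## artifacts: Poisson-placed saturating excursions, merged if touching
    nArt <- stats::rpois(1, config$artifactRate * durationSec / 3600)
    artIv <- data.frame(start = numeric(0), end = numeric(0))
    if (nArt > 0) {
      s <- sort(stats::runif(nArt, 0, durationSec - config$artifactDurationSec))
      e <- s + config$artifactDurationSec
      keepStart <- s[1]; starts <- numeric(0); ends <- numeric(0)
      curEnd <- e[1]
      for (i in seq_along(s)[-1]) {
        if (s[i] <= curEnd) curEnd <- max(curEnd, e[i])
        else { starts <- c(starts, keepStart); ends <- c(ends, curEnd)
               keepStart <- s[i]; curEnd <- e[i] }
      }
      starts <- c(starts, keepStart); ends <- c(ends, curEnd)
      artIv <- data.frame(start = starts, end = ends)
      eegTrace <- injectArtifacts(eegTrace, artIv,
                                  config$artifactAmplitudeMv, fs)
    }

    expectation <- config$stateBandAmplitudes^2 / 2

    rec <- telemetryRecording(
      eeg = eegTrace, emg = emgTrace, activity = act,
      samplingRate = fs, startClockHour = config$startClockHour,
      lightOnsetHour = config$lightOnsetHour,
      lightOffsetHour = config$lightOffsetHour,
      subjectId = sprintf("sim%d", config$rngSeed), groupLabel = "sim")
    truth <- new("SimGroundTruth",
      stateSequence = states, spikes = spikes, artifactIntervals = artIv,
      bandPowerExpectation = expectation, unitSd = unitSd)
    list(recording = rec, truth = truth)
  })
}

## TRUE when a clock hour falls in the lights-on phase [on, off).
inLightPhase <- function(clockHour, lightOnsetHour, lightOffsetHour) {
  h <- clockHour %% 24
  if (lightOnsetHour <= lightOffsetHour)
    h >= lightOnsetHour & h < lightOffsetHour
  else
    h >= lightOnsetHour | h < lightOffsetHour
}
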
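## Memoized simulation fixtures shared across test files. Everything is
## generated in code at test time; seeds are fixed so the suite is
## deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, code) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(code), envir = .fixtures)
  get(name, envir = .fixtures)
}

## 2 h mixed-state recording with moderate spiking (default amplitudes)
simSmall <- function() fixture("simSmall",
  simulateRecording(simConfig(durationHours = 2, rngSeed = 3,
                              spikeRates = c(A = 2, B = 3, C = 1))))

simSmallReport <- function() fixture("simSmallReport",
  analyzeSubject(simSmall()$recording))

## 1 h NREM-only recording, delta oscillation only
simNrem <- function() fixture("simNrem", {
  amps <- matrix(0, 3, 5, dimnames = dimnames(defaultStateAmplitudes()))
  amps["NREM", "delta"] <- 0.2
  simulateRecording(simConfig(durationHours = 1, rngSeed = 4,
                              stateBandAmplitudes = amps,
                              fixedState = "NREM"))
})

simNremFrames <- function() fixture("simNremFrames", {
  rec <- simNrem()$recording
  spectrogramMedianBins(highpassFilter(eeg(rec), 0.5, samplingRate(rec)),
                        samplingRate(rec))
})

## minute table with an exact linear activity relationship in every band
linearMinuteTable <- function(n = 60, slope = 3, intercept = 2) {
  act <- rep(0:9, length.out = n)
  bands <- defaultBands()$band
  mp <- data.frame(minute = seq_len(n) - 1)
  for (b in bands) mp[[b]] <- intercept + slope * act
  mp$total <- rowSums(mp[, bands])
  mp$nFrames <- 6L
  mp$missing <- FALSE
  mp$activity <- act
  mp
}
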
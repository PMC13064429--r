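Package: eegtel
Title: Rodent EEG/EMG Telemetry Analysis: Spectral Power, Epileptiform
    Spikes, and Sleep Staging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for continuous wireless-telemetry
    electrocorticography (EEG) and electromyography (EMG) recordings from
    mice, with a parallel per-minute locomotor-activity channel and a
    light/dark schedule. Implements amplitude-based artifact rejection,
    zero-phase FIR high-pass filtering, a median-power spectrogram in 10 s
    bins, minute-level band power with tenth-percentile normalization,
    circadian (zeitgeber-time) hourly profiles, percent-of-total power,
    per-band power-versus-activity regression with a delta-slope quality
    control rule, amplitude-threshold epileptiform spike detection with
    waveform-duration filtering and morphological classification, and
    rule-based wake/NREM/REM sleep staging in 10 s epochs with bout and
    stage summaries. A synthetic telemetry generator with a hidden
    semi-Markov sleep-state sequence, 1/f background, state-dependent band
    oscillations, injected spike waveforms and artifacts provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
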
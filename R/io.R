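## Minimal EDF (European Data Format) reader/writer: 16-bit samples,
## 1 s data records, ASCII headers. No EDF package is available in this
## stack, and the format is simple enough to support directly for the
## two-channel telemetry traces this package consumes.

padField <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write voltage channels to an EDF file
#'
#' @param path output file.
#' @param channels named list of numeric traces (mV), equal lengths.
#' @param samplingRate sampling rate (Hz) shared by all channels.
#' @param startClockHour recording start clock hour (stored in the EDF
#'   start-time field).
#' @param physicalRangeMv symmetric physical range; samples are clipped
#'   to it before 16-bit quantization.
#' @return Invisibly `path`.
#' @export
writeEDF <- function(path, channels, samplingRate,
                     startClockHour = 6, physicalRangeMv = 5) {
  ns <- length(channels)
  stopifnot(ns >= 1, !is.null(names(channels)))
  n <- unique(vapply(channels, length, integer(1)))
  stopifnot(length(n) == 1)
  spr <- as.integer(samplingRate)          # samples per 1 s record
  nrec <- ceiling(n / spr)
  h <- startClockHour %% 24
  startTime <- sprintf("%02d.%02d.%02d", floor(h), floor((h * 60) %% 60),
                       floor((h * 3600) %% 60))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    padField("0", 8), padField("X X X X", 80), padField("Startdate 01-JAN-2000", 80),
    padField("01.01.00", 8), padField(startTime, 8),
    padField(256 * (1 + ns), 8), padField("", 44),
    padField(nrec, 8), padField(1, 8), padField(ns, 4)),
    con, eos = NULL)
  fields <- list(
    label = function(nm) padField(nm, 16),
    transducer = function(nm) padField("", 80),
    dim = function(nm) padField("mV", 8),
    pmin = function(nm) padField(-physicalRangeMv, 8),
    pmax = function(nm) padField(physicalRangeMv, 8),
    dmin = function(nm) padField(-32767L, 8),
    dmax = function(nm) padField(32767L, 8),
    prefilter = function(nm) padField("", 80),
    spr = function(nm) padField(spr, 8),
    reserved = function(nm) padField("", 32))
  for (f in fields)
    for (nm in names(channels)) writeChar(f(nm), con, eos = NULL)
  scale <- 32767 / physicalRangeMv
  dig <- lapply(channels, function(x) {
    x <- c(x, numeric(nrec * spr - length(x)))
    as.integer(round(pmax(pmin(x, physicalRangeMv), -physicalRangeMv) * scale))
  })
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (nm in names(channels))
      writeBin(dig[[nm]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file written by [writeEDF()] or any standard 16-bit
#'   EDF with a uniform record layout.
#' @return list with `channels` (named list of numeric traces, physical
#'   units), `samplingRate` per channel, `startClockHour`.
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8)
  startTime <- rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per <- function(k) vapply(seq_len(ns), function(i) rd(k), character(1))
  labels <- per(16); per(80); per(8)
  pmin <- as.numeric(per(8)); pmax <- as.numeric(per(8))
  dmin <- as.numeric(per(8)); dmax <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8)); per(32)
  dat <- lapply(seq_len(ns), function(i) numeric(nrec * spr[i]))
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      dat[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (v - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
    }
  }
  names(dat) <- labels
  hms <- as.numeric(strsplit(startTime, ".", fixed = TRUE)[[1]])
  list(channels = dat, samplingRate = spr / recDur,
       startClockHour = hms[1] + hms[2] / 60 + hms[3] / 3600)
}

#' Write a recording (and optional ground truth) to a directory
#'
#' Emits `recording.edf` (EEG + EMG), `activity.csv`
#' (`minute,activity_count`), `meta.csv` (light schedule, labels), and,
#' when ground truth is supplied, `truth_states.csv`, `truth_spikes.csv`
#' and `truth_artifacts.csv`.
#'
#' @param rec a [TelemetryRecording-class].
#' @param dir output directory (created if needed).
#' @param truth optional [SimGroundTruth-class].
#' @return Invisibly `dir`.
#' @export
writeRecording <- function(rec, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEDF(file.path(dir, "recording.edf"),
           list(EEG = eeg(rec), EMG = emg(rec)),
           samplingRate = samplingRate(rec),
           startClockHour = startClockHour(rec))
  utils::write.csv(
    data.frame(minute = seq_along(activity(rec)) - 1L,
               activity_count = activity(rec)),
    file.path(dir, "activity.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(key = c("samplingRate", "startClockHour", "lightOnsetHour",
                       "lightOffsetHour", "subjectId", "groupLabel"),
               value = c(samplingRate(rec), startClockHour(rec),
                         lightOnsetHour(rec), lightOffsetHour(rec),
                         subjectId(rec), groupLabel(rec))),
    file.path(dir, "meta.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(data.frame(epoch = seq_along(stateSequence(truth)),
                                stage = stateSequence(truth)),
                     file.path(dir, "truth_states.csv"), row.names = FALSE)
    utils::write.csv(spikeTruth(truth), file.path(dir, "truth_spikes.csv"),
                     row.names = FALSE)
    utils::write.csv(artifactIntervals(truth),
                     file.path(dir, "truth_artifacts.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a recording from EDF + CSV
#'
#' @param dir a directory written by [writeRecording()], or use `edfPath`
#'   and `activityPath` directly.
#' @param edfPath,activityPath explicit file paths (override `dir`).
#' @param channelMap named character vector mapping the roles `eeg` and
#'   `emg` to EDF channel labels.
#' @param samplingRate optional expected sampling rate; a mismatch with
#'   the file is an error.
#' @return A [TelemetryRecording-class]. Gaps in the activity CSV
#'   (absent minutes) become `NA`, not zero.
#' @export
readRecording <- function(dir = NULL, edfPath = NULL, activityPath = NULL,
                          channelMap = c(eeg = "EEG", emg = "EMG"),
                          samplingRate = NULL) {
  if (!is.null(dir)) {
    if (is.null(edfPath)) edfPath <- file.path(dir, "recording.edf")
    if (is.null(activityPath)) activityPath <- file.path(dir, "activity.csv")
  }
  if (!file.exists(edfPath)) stop("EDF file not found: ", edfPath)
  edf <- readEDF(edfPath)
  for (role in c("eeg", "emg"))
    if (!channelMap[[role]] %in% names(edf$channels))
      stop("EDF is missing the '", channelMap[[role]], "' (", role, ") channel")
  fs <- edf$samplingRate[[match(channelMap[["eeg"]], names(edf$channels))]]
  if (!is.null(samplingRate) && abs(fs - samplingRate) > 1e-9)
    stop("sampling rate mismatch: file has ", fs, " Hz, expected ", samplingRate)

  meta <- list(startClockHour = edf$startClockHour,
               lightOnsetHour = 6, lightOffsetHour = 18,
               subjectId = basename(edfPath), groupLabel = "unknown")
  metaPath <- if (!is.null(dir)) file.path(dir, "meta.csv") else NULL
  if (!is.null(metaPath) && file.exists(metaPath)) {
    mtab <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
    mv <- stats::setNames(mtab$value, mtab$key)
    for (k in c("startClockHour", "lightOnsetHour", "lightOffsetHour"))
      if (k %in% names(mv)) meta[[k]] <- as.numeric(mv[[k]])
    for (k in c("subjectId", "groupLabel"))
      if (k %in% names(mv)) meta[[k]] <- mv[[k]]
  }
  eegTrace <- edf$channels[[channelMap[["eeg"]]]]
  emgTrace <- edf$channels[[channelMap[["emg"]]]]
  nMin <- ceiling(length(eegTrace) / fs / 60)
  act <- rep(NA_real_, nMin)
  if (!is.null(activityPath) && file.exists(activityPath)) {
    atab <- utils::read.csv(activityPath)
    ok <- atab$minute >= 0 & atab$minute < nMin
    act[atab$minute[ok] + 1L] <- atab$activity_count[ok]
  }
  telemetryRecording(eegTrace, emgTrace, act, samplingRate = fs,
                     startClockHour = meta$startClockHour,
                     lightOnsetHour = meta$lightOnsetHour,
                     lightOffsetHour = meta$lightOffsetHour,
                     subjectId = meta$subjectId, groupLabel = meta$groupLabel)
}
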
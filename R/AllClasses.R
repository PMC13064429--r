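#' @import methods
NULL

#' TelemetryRecording: one subject's synchronized telemetry channels
#'
#' Container for a single mouse's continuous EEG and EMG voltage traces
#' (mV, sampled at `samplingRate` Hz), the parallel per-minute locomotor
#' activity counts, the wall-clock start time and the light/dark schedule.
#'
#' @slot eeg numeric vector, EEG in mV.
#' @slot emg numeric vector, EMG in mV, same length as `eeg`.
#' @slot activity numeric vector of per-minute activity counts
#'   (length `ceiling(duration / 60 s)`); `NA` marks missing minutes.
#' @slot samplingRate sampling rate in Hz.
#' @slot startClockHour wall-clock hour of the first sample (0-24).
#' @slot lightOnsetHour,lightOffsetHour clock hours when lights switch
#'   on and off (ZT0 corresponds to `lightOnsetHour`).
#' @slot subjectId,groupLabel identity labels.
#'
#' @seealso [telemetryRecording()], [simulateRecording()]
#' @export
setClass("TelemetryRecording",
  representation(
    eeg = "numeric",
    emg = "numeric",
    activity = "numeric",
    samplingRate = "numeric",
    startClockHour = "numeric",
    lightOnsetHour = "numeric",
    lightOffsetHour = "numeric",
    subjectId = "character",
    groupLabel = "character"
  ),
  prototype(
    samplingRate = 500,
    startClockHour = 6,
    lightOnsetHour = 6,
    lightOffsetHour = 18,
    subjectId = "subject",
    groupLabel = "group"
  )
)

setValidity("TelemetryRecording", function(object) {
  msg <- character()
  if (length(object@eeg) != length(object@emg))
    msg <- c(msg, "eeg and emg must have equal length")
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  nmin <- ceiling(length(object@eeg) / object@samplingRate / 60)
  if (length(object@activity) != nmin)
    msg <- c(msg, sprintf(
      "activity must have one entry per started minute (%d, got %d)",
      nmin, length(object@activity)))
  if (object@startClockHour < 0 || object@startClockHour >= 24)
    msg <- c(msg, "startClockHour must lie in [0, 24)")
  if (length(msg)) msg else TRUE
})

#' Construct a TelemetryRecording
#'
#' @param eeg,emg numeric voltage traces (mV) of equal length.
#' @param activity per-minute activity counts (`NA` = missing minute).
#' @param samplingRate sampling rate in Hz.
#' @param startClockHour clock hour of the first sample.
#' @param lightOnsetHour,lightOffsetHour light schedule (clock hours).
#' @param subjectId,groupLabel identity labels.
#' @return A [TelemetryRecording-class] object.
#' @examples
#' fs <- 500
#' rec <- telemetryRecording(
#'   eeg = rnorm(fs * 120, sd = 0.05), emg = rnorm(fs * 120, sd = 0.02),
#'   activity = c(3, 0), samplingRate = fs)
#' durationHours(rec)
#' @export
telemetryRecording <- function(eeg, emg, activity,
                               samplingRate = 500,
                               startClockHour = 6,
                               lightOnsetHour = 6, lightOffsetHour = 18,
                               subjectId = "subject", groupLabel = "group") {
  new("TelemetryRecording",
    eeg = as.numeric(eeg), emg = as.numeric(emg),
    activity = as.numeric(activity),
    samplingRate = samplingRate, startClockHour = startClockHour,
    lightOnsetHour = lightOnsetHour, lightOffsetHour = lightOffsetHour,
    subjectId = subjectId, groupLabel = groupLabel)
}

#' SimGroundTruth: the hidden truth behind a simulated recording
#'
#' @slot stateSequence character vector, one stage label
#'   (`"wake"`, `"NREM"`, `"REM"`) per 10 s epoch.
#' @slot spikes data.frame with columns `time` (s, peak), `class`
#'   (`"A"|"B"|"C"`) and `amplitude` (multiples of the unit SD).
#' @slot artifactIntervals data.frame with columns `start`, `end` (s),
#'   disjoint and sorted.
#' @slot bandPowerExpectation state x band matrix of the expected
#'   oscillatory band power (mV^2, A^2/2 per enabled sinusoid).
#' @slot unitSd the robust SD (mV) of the 6.3 Hz high-passed spike-free
#'   trace, the unit in which spike amplitudes are expressed.
#' @export
setClass("SimGroundTruth",
  representation(
    stateSequence = "character",
    spikes = "data.frame",
    artifactIntervals = "data.frame",
    bandPowerExpectation = "matrix",
    unitSd = "numeric"
  )
)

setValidity("SimGroundTruth", function(object) {
  msg <- character()
  ai <- object@artifactIntervals
  if (nrow(ai)) {
    if (any(ai$end <= ai$start)) msg <- c(msg, "artifact intervals must have end > start")
    if (is.unsorted(ai$start) ||
        any(ai$start[-1] < ai$end[-nrow(ai)]))
      msg <- c(msg, "artifact intervals must be sorted and disjoint")
  }
  if (length(msg)) msg else TRUE
})

## ---- generics -------------------------------------------------------------

#' Accessors for TelemetryRecording and SimGroundTruth
#'
#' @param object a [TelemetryRecording-class] or [SimGroundTruth-class].
#' @return The corresponding slot value; `durationHours()` returns the
#'   recording length in hours.
#' @name telemetry-accessors
#' @aliases eeg emg activity samplingRate subjectId groupLabel
#'   startClockHour lightOnsetHour lightOffsetHour durationHours
#'   stateSequence spikeTruth artifactIntervals
NULL

#' @rdname telemetry-accessors
#' @export
setGeneric("eeg", function(object) standardGeneric("eeg"))
#' @rdname telemetry-accessors
#' @export
setGeneric("eeg<-", function(object, value) standardGeneric("eeg<-"))
#' @rdname telemetry-accessors
#' @export
setGeneric("emg", function(object) standardGeneric("emg"))
#' @rdname telemetry-accessors
#' @export
setGeneric("activity", function(object) standardGeneric("activity"))
#' @rdname telemetry-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname telemetry-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname telemetry-accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname telemetry-accessors
#' @export
setGeneric("startClockHour", function(object) standardGeneric("startClockHour"))
#' @rdname telemetry-accessors
#' @export
setGeneric("lightOnsetHour", function(object) standardGeneric("lightOnsetHour"))
#' @rdname telemetry-accessors
#' @export
setGeneric("lightOffsetHour", function(object) standardGeneric("lightOffsetHour"))
#' @rdname telemetry-accessors
#' @export
setGeneric("durationHours", function(object) standardGeneric("durationHours"))
#' @rdname telemetry-accessors
#' @export
setGeneric("stateSequence", function(object) standardGeneric("stateSequence"))
#' @rdname telemetry-accessors
#' @export
setGeneric("spikeTruth", function(object) standardGeneric("spikeTruth"))
#' @rdname telemetry-accessors
#' @export
setGeneric("artifactIntervals", function(object) standardGeneric("artifactIntervals"))

#' @rdname telemetry-accessors
setMethod("eeg", "TelemetryRecording", function(object) object@eeg)
#' @rdname telemetry-accessors
#' @param value replacement EEG trace (same length).
setMethod("eeg<-", "TelemetryRecording", function(object, value) {
  object@eeg <- as.numeric(value)
  validObject(object)
  object
})
#' @rdname telemetry-accessors
setMethod("emg", "TelemetryRecording", function(object) object@emg)
#' @rdname telemetry-accessors
setMethod("activity", "TelemetryRecording", function(object) object@activity)
#' @rdname telemetry-accessors
setMethod("samplingRate", "TelemetryRecording", function(object) object@samplingRate)
#' @rdname telemetry-accessors
setMethod("subjectId", "TelemetryRecording", function(object) object@subjectId)
#' @rdname telemetry-accessors
setMethod("groupLabel", "TelemetryRecording", function(object) object@groupLabel)
#' @rdname telemetry-accessors
setMethod("startClockHour", "TelemetryRecording", function(object) object@startClockHour)
#' @rdname telemetry-accessors
setMethod("lightOnsetHour", "TelemetryRecording", function(object) object@lightOnsetHour)
#' @rdname telemetry-accessors
setMethod("lightOffsetHour", "TelemetryRecording", function(object) object@lightOffsetHour)
#' @rdname telemetry-accessors
setMethod("durationHours", "TelemetryRecording", function(object)
  length(object@eeg) / object@samplingRate / 3600)

#' @rdname telemetry-accessors
setMethod("stateSequence", "SimGroundTruth", function(object) object@stateSequence)
#' @rdname telemetry-accessors
setMethod("spikeTruth", "SimGroundTruth", function(object) object@spikes)
#' @rdname telemetry-accessors
setMethod("artifactIntervals", "SimGroundTruth", function(object) object@artifactIntervals)

setMethod("show", "TelemetryRecording", function(object) {
  cat(sprintf(
    "TelemetryRecording '%s' (group '%s')\n  %.2f h @ %g Hz (%d samples/channel)\n",
    object@subjectId, object@groupLabel, durationHours(object),
    object@samplingRate, length(object@eeg)))
  cat(sprintf("  activity: %d minutes (%d missing)\n",
              length(object@activity), sum(is.na(object@activity))))
  cat(sprintf("  clock start %.1f h, lights on %g-%g h\n",
              object@startClockHour, object@lightOnsetHour,
              object@lightOffsetHour))
})

setMethod("show", "SimGroundTruth", function(object) {
  tab <- table(factor(object@spikes$class, levels = c("A", "B", "C")))
  cat(sprintf(
    "SimGroundTruth: %d epochs (%s), %d spikes (A=%d B=%d C=%d), %d artifact intervals\n",
    length(object@stateSequence),
    paste(sprintf("%s %.0f%%",
                  names(table(object@stateSequence)),
                  100 * table(object@stateSequence) /
                    max(1, length(object@stateSequence))),
          collapse = ", "),
    nrow(object@spikes), tab[["A"]], tab[["B"]], tab[["C"]],
    nrow(object@artifactIntervals)))
})
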
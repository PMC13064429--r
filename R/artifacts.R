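#' Amplitude-based artifact rejection
#'
#' Marks every sample whose absolute voltage reaches the cutoff, plus a
#' symmetric pad around each excursion, as artifact. Masked samples are
#' excluded from all downstream aggregation (never interpolated); in the
#' returned `cleaned` trace they are set to zero purely so that the
#' subsequent FIR filtering stays well-behaved, and the mask travels with
#' the data so those stretches are dropped from spectrogram windows,
#' spike detection and rate denominators.
#'
#' @param x numeric voltage series (mV).
#' @param cutoffMv rejection cutoff in mV (default 2, i.e. the
#'   -2 to +2 mV window of usable signal).
#' @param padMs pad masked on each side of an excursion (ms); filter
#'   ringing around clipped excursions contaminates neighbours.
#' @param samplingRate sampling rate (Hz), needed to convert `padMs`.
#' @return list with `cleaned` (masked samples zeroed), `mask` (logical,
#'   `TRUE` = rejected), `fraction` (fraction of samples masked) and
#'   `cutoffMv`.
#' @examples
#' fs <- 500
#' x <- rnorm(fs, sd = 0.1); x[250] <- 2.5
#' removeArtifacts(x, samplingRate = fs, padMs = 0)$fraction * fs  # 1 sample
#' @export
removeArtifacts <- function(x, cutoffMv = 2, padMs = 100, samplingRate = 500) {
  stopifnot(cutoffMv > 0, padMs >= 0)
  n <- length(x)
  if (n == 0)
    return(list(cleaned = x, mask = logical(0), fraction = 0, cutoffMv = cutoffMv))
  mask <- abs(x) >= cutoffMv
  if (any(mask) && padMs > 0) {
    pad <- round(padMs / 1000 * samplingRate)
    if (pad > 0) {
      ## dilate the mask by `pad` samples on each side
      idx <- which(mask)
      lo <- pmax(idx - pad, 1L)
      hi <- pmin(idx + pad, n)
      d <- integer(n + 1L)
      d[lo] <- d[lo] + 1L
      d[hi + 1L] <- d[hi + 1L] - 1L
      mask <- cumsum(d[seq_len(n)]) > 0L
    }
  }
  cleaned <- x
  cleaned[mask] <- 0
  list(cleaned = cleaned, mask = mask, fraction = mean(mask), cutoffMv = cutoffMv)
}

#' Convert a sample mask to time intervals
#'
#' @param mask logical vector, `TRUE` = masked.
#' @param samplingRate sampling rate (Hz).
#' @return data.frame with `start`, `end` in seconds (end exclusive).
#' @export
maskToIntervals <- function(mask, samplingRate) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep] / samplingRate,
             end = ends[keep] / samplingRate)
}

#' Interval-level Jaccard index between two interval sets
#'
#' Intervals from each set are matched one-to-one by overlap (greedy, in
#' order); the index is matched / (nA + nB - matched). Used to score how
#' well the artifact mask recovers injected artifact intervals.
#'
#' @param a,b data.frames with `start`, `end` columns (seconds).
#' @return Jaccard index in \[0, 1\]; 1 when both sets are empty.
#' @export
intervalJaccard <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  a <- a[order(a$start), ]; b <- b[order(b$start), ]
  usedB <- logical(nb)
  matched <- 0L
  for (i in seq_len(na)) {
    j <- which(!usedB & b$start < a$end[i] & b$end > a$start[i])
    if (length(j)) {
      usedB[j[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  matched / (na + nb - matched)
}

#' Inject saturating artifacts into a voltage trace
#'
#' Replaces the samples inside each interval with a saturating square-wave
#' excursion of the given amplitude (alternating sign at 12.5 Hz), so that
#' every injected sample exceeds the +/-2 mV cleaning cutoff.
#'
#' @param x numeric voltage series (mV).
#' @param intervals data.frame with `start`, `end` (seconds, end
#'   exclusive), inside the recording.
#' @param amplitudeMv excursion amplitude; must exceed 2 mV or the
#'   cleaning stage could not see it.
#' @param samplingRate sampling rate (Hz).
#' @return The trace with artifacts written over the intervals.
#' @export
injectArtifacts <- function(x, intervals, amplitudeMv = 3, samplingRate = 500) {
  if (amplitudeMv <= 2)
    stop("artifact amplitude must exceed the 2 mV cleaning cutoff")
  if (is.null(intervals) || nrow(intervals) == 0) return(x)
  n <- length(x)
  if (any(intervals$start < 0) || any(intervals$end * samplingRate > n + 1e-6))
    stop("artifact intervals must lie within the recording")
  for (i in seq_len(nrow(intervals))) {
    i0 <- floor(intervals$start[i] * samplingRate) + 1L
    i1 <- min(ceiling(intervals$end[i] * samplingRate), n)
    idx <- i0:i1
    phase <- floor((idx - i0) / samplingRate * 25) %% 2
    x[idx] <- amplitudeMv * ifelse(phase == 0, 1, -1)
  }
  x
}
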
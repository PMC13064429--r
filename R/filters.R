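#' Design a zero-phase FIR high-pass filter
#'
#' Hamming-windowed linear-phase FIR design (odd length, type I), sized so
#' the stopband reaches at least 40 dB attenuation at half the cutoff and
#' the passband is flat (ripple below 1 dB) from twice the cutoff upward.
#'
#' @param cutoffHz -6 dB cutoff frequency (Hz).
#' @param samplingRate sampling rate (Hz).
#' @param maxTaps safety cap on the filter length.
#' @return numeric vector of symmetric filter coefficients (odd length).
#' @keywords internal
designFirHighpass <- function(cutoffHz, samplingRate, maxTaps = 20001L) {
  if (cutoffHz <= 0 || cutoffHz >= samplingRate / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  ## Hamming transition width ~ 3.3/N cycles/sample; the transition must
  ## fit between cutoff/2 (stop edge) and 2*cutoff (pass edge).
  n <- ceiling(3.3 * samplingRate / (0.8 * cutoffHz))
  n <- min(n, maxTaps - 1L)
  if (n %% 2 == 1) n <- n + 1  # even order -> odd length, integer delay
  signal::fir1(n, cutoffHz / (samplingRate / 2), type = "high")
}

## FFT overlap-save FIR convolution returning the full convolution
## trimmed to "same" alignment with the given integer delay.
firApply <- function(b, x, delay = (length(b) - 1L) %/% 2L) {
  nb <- length(b)
  nx <- length(x)
  if (nx == 0) return(x)
  if (nx <= 4 * nb) {
    y <- stats::convolve(c(x, numeric(nb - 1)), rev(b), conj = TRUE, type = "open")
    ## convolve(type="open") returns length nx+2*(nb-1)-1; take full conv part
    y <- y[seq_len(nx + nb - 1)]
    return(y[delay + seq_len(nx)])
  }
  L <- max(2^ceiling(log2(8 * nb)), 2^14)
  step <- L - nb + 1L
  H <- stats::fft(c(b, numeric(L - nb)))
  xp <- c(numeric(nb - 1L), x, numeric(L))
  out <- numeric(nx + nb - 1L)
  pos <- 1L
  total <- nx + nb - 1L
  while (pos <= total) {
    seg <- xp[pos:(pos + L - 1L)]
    y <- Re(stats::fft(stats::fft(seg) * H, inverse = TRUE)) / L
    keep <- min(step, total - pos + 1L)
    out[pos:(pos + keep - 1L)] <- y[nb:(nb + keep - 1L)]
    pos <- pos + step
  }
  out[delay + seq_len(nx)]
}

#' Zero-phase FIR high-pass filtering
#'
#' Applies a symmetric (linear-phase) FIR high-pass filter with exact
#' group-delay compensation, so the output is zero-phase: spike timing and
#' epoch alignment are preserved. The two analysis branches use this with
#' different cutoffs (0.5 Hz for the spectral branch, 6.3 Hz for the spike
#' branch) on the same raw trace.
#'
#' @param x numeric voltage series (mV).
#' @param cutoffHz high-pass cutoff (Hz); must be below Nyquist.
#' @param samplingRate sampling rate (Hz).
#' @param coef optional precomputed coefficients from
#'   [designFirHighpass()]; pass these when filtering many traces with
#'   the same design.
#' @return Filtered series, same length as `x`.
#' @examples
#' fs <- 500
#' t <- seq(0, 10, by = 1 / fs)
#' y <- highpassFilter(sin(2 * pi * 10 * t) + 2, cutoffHz = 0.5,
#'                     samplingRate = fs)
#' sd(y[fs:(9 * fs)]) * sqrt(2)  # ~1: the DC offset is gone, tone kept
#' @export
highpassFilter <- function(x, cutoffHz, samplingRate, coef = NULL) {
  if (is.null(coef)) coef <- designFirHighpass(cutoffHz, samplingRate)
  firApply(coef, x)
}
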
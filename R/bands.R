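#' Conventional rodent EEG frequency bands tiling 0.5-80 Hz
#'
#' Band edges are half-open `[low, high)` except the last band, which
#' includes its upper edge, so the bands tile the analysis range exactly
#' and per-band powers sum to the total power.
#'
#' @param edges named numeric vector of interior edges; the defaults give
#'   delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-80 Hz.
#' @return data.frame with columns `band`, `low`, `high`.
#' @examples
#' defaultBands()
#' @export
defaultBands <- function(edges = c(delta = 0.5, theta = 4, alpha = 8,
                                   beta = 13, gamma = 30, top = 80)) {
  stopifnot(length(edges) >= 3, !is.unsorted(edges, strictly = TRUE))
  data.frame(
    band = names(edges)[-length(edges)],
    low = unname(edges[-length(edges)]),
    high = unname(edges[-1]),
    stringsAsFactors = FALSE
  )
}

#' Assert that a band table tiles a frequency range
#'
#' @param bands a band table as returned by [defaultBands()].
#' @param fmin,fmax range that must be tiled exactly.
#' @return Invisibly `bands`, or an error if the bands overlap, leave
#'   gaps, or do not span `[fmin, fmax]`.
#' @keywords internal
checkBandTiling <- function(bands, fmin = 0.5, fmax = 80) {
  stopifnot(is.data.frame(bands), all(c("band", "low", "high") %in% names(bands)))
  bands <- bands[order(bands$low), ]
  if (abs(bands$low[1] - fmin) > 1e-9 ||
      abs(bands$high[nrow(bands)] - fmax) > 1e-9 ||
      any(abs(bands$low[-1] - bands$high[-nrow(bands)]) > 1e-9))
    stop("bands must tile [", fmin, ", ", fmax, "] Hz contiguously")
  invisible(bands)
}

## Map frequency gridpoints to band labels (NA outside all bands).
## Last band is closed above so fmax itself is counted.
bandOfFrequency <- function(freqs, bands) {
  bands <- bands[order(bands$low), ]
  lab <- rep(NA_character_, length(freqs))
  for (i in seq_len(nrow(bands))) {
    inb <- freqs >= bands$low[i] &
      (if (i == nrow(bands)) freqs <= bands$high[i] else freqs < bands$high[i])
    lab[inb] <- bands$band[i]
  }
  lab
}
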
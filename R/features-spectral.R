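# Octave-spaced sub-band edges over the breathing-sound analysis band.
.bandEdges <- c(75, 150, 300, 600, 1200, 2400, 3000)

#' Spectral features of one breath phase
#'
#' Welch power-spectral-density summaries: total in-band power, per-band
#' power over octave-spaced sub-bands of 75-3000 Hz, spectral centroid, and
#' normalized spectral entropy `H = -sum p log p / log N` over the
#' PSD-derived distribution (1 for a flat spectrum, near 0 for a tone).
#'
#' @param x numeric phase signal (>= 256 samples)
#' @param rate sampling rate in Hz
#' @param nfft Welch segment length
#' @return Named numeric vector; all `NA` when the phase is too short.
#' @export
spectralFeatures <- function(x, rate, nfft = 256L) {
  nms <- c(sprintf("sp_power_b%d", seq_len(length(.bandEdges) - 1L)),
           "sp_total", "sp_centroid", "sp_entropy")
  if (length(x) < 256L) return(stats::setNames(rep(NA_real_, length(nms)), nms))
  w <- welchPsd(x, rate, nfft = nfft)
  bp <- vapply(seq_len(length(.bandEdges) - 1L), function(b) {
    sel <- w$freq >= .bandEdges[b] & w$freq < .bandEdges[b + 1L]
    sum(w$psd[sel])
  }, numeric(1))
  inBand <- w$freq >= .bandEdges[1] & w$freq < .bandEdges[length(.bandEdges)]
  total <- sum(w$psd[inBand])
  centroid <- sum(w$freq * w$psd) / sum(w$psd)
  p <- w$psd / sum(w$psd)
  ent <- entropyBits(p) / log2(length(p))
  stats::setNames(c(bp, total, centroid, ent), nms)
}
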
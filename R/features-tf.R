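# Symlet-4 decomposition filters (orthonormal, 8 taps).
.sym4Lo <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
             0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
             -0.01260396726203783, 0.03222310060404270)
.sym4Hi <- c(-0.03222310060404270, -0.01260396726203783, 0.09921954357684722,
             0.29785779560527736, -0.80373875180591614, 0.49761866763201545,
             0.02963552764599851, -0.07576571478927333)

# One periodized analysis step: returns list(approx, detail), each length n/2.
.dwtStep <- function(a) {
  n <- length(a)
  k <- seq(0L, n - 2L, by = 2L)
  idx <- outer(k, 0:7, "+") %% n + 1L
  am <- matrix(a[idx], nrow = length(k))
  list(approx = as.numeric(am %*% .sym4Lo),
       detail = as.numeric(am %*% .sym4Hi))
}

#' Periodized Symlet-4 discrete wavelet transform
#'
#' Orthonormal 4-level (by default) analysis with periodic boundary
#' handling, so total coefficient energy equals signal energy exactly.
#' Input is truncated to a multiple of `2^levels`.
#'
#' @param x numeric signal
#' @param levels decomposition depth
#' @return Named list of coefficient vectors `D1..D{levels}` and
#'   `A{levels}` (finest to coarsest detail, then approximation).
#' @export
dwtSym4 <- function(x, levels = 4L) {
  n <- (length(x) %/% 2^levels) * 2^levels
  if (n < 2^levels) stop("signal too short for ", levels, "-level DWT")
  a <- x[seq_len(n)]
  out <- list()
  for (j in seq_len(levels)) {
    st <- .dwtStep(a)
    out[[paste0("D", j)]] <- st$detail
    a <- st$approx
  }
  out[[paste0("A", levels)]] <- a
  out
}

# Constant-Q filterbank band energies from the FFT power spectrum:
# geometrically spaced centers (binsPerOctave per octave) over [fMin, fMax],
# each band integrating power over +/- half a bin spacing.
cqtBandEnergies <- function(x, rate, fMin = 75, fMax = 3000, binsPerOctave = 12L) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  pw <- Mod(X[seq_len(n %/% 2L + 1L)])^2 / n
  freq <- (0:(n %/% 2L)) * rate / n
  nBins <- floor(log2(fMax / fMin) * binsPerOctave) + 1L
  fc <- fMin * 2^((seq_len(nBins) - 1L) / binsPerOctave)
  halfStep <- 2^(1 / (2 * binsPerOctave))
  e <- vapply(fc, function(f) sum(pw[freq >= f / halfStep & freq < f * halfStep]),
              numeric(1))
  list(fc = fc, energy = e)
}

#' Time-frequency features of one breath phase
#'
#' Four-level Symlet-4 wavelet sub-band summaries (relative energy and
#' normalized log-energy entropy per sub-band A4, D4..D1) plus constant-Q
#' band energies (12 bins/octave over 75-3000 Hz) summarized as mean log
#' energy per octave.
#'
#' @param x numeric phase signal
#' @param rate sampling rate in Hz
#' @return Named numeric vector; all `NA` when the phase is shorter than
#'   `2^4` times the filter length.
#' @export
tfFeatures <- function(x, rate) {
  octaves <- c(75, 150, 300, 600, 1200, 2400, 3000)
  bands <- c("A4", "D4", "D3", "D2", "D1")
  nms <- c(sprintf("tf_wav_energy_%s", bands), sprintf("tf_wav_entropy_%s", bands),
           sprintf("tf_cqt_oct%d", seq_len(length(octaves) - 1L)))
  if (length(x) < 16L * 8L) return(stats::setNames(rep(NA_real_, length(nms)), nms))
  dw <- dwtSym4(x, 4L)
  en <- vapply(dw[bands], function(c) sum(c^2), numeric(1))
  rel <- if (sum(en) > 0) en / sum(en) else en * NA_real_
  sent <- vapply(dw[bands], function(c) {
    p <- c^2 / (sum(c^2) + 1e-30)
    if (length(p) < 2L) return(0)
    entropyBits(p) / log2(length(p))
  }, numeric(1))
  cq <- cqtBandEnergies(x, rate, octaves[1], octaves[length(octaves)])
  oct <- findInterval(cq$fc, octaves, rightmost.closed = TRUE)
  cqm <- vapply(seq_len(length(octaves) - 1L), function(o) {
    sel <- oct == o
    if (!any(sel)) return(NA_real_)
    mean(log10(cq$energy[sel] + 1e-20))
  }, numeric(1))
  stats::setNames(c(rel, sent, cqm), nms)
}
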
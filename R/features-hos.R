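#' Direct bispectrum and squared bicoherence estimate
#'
#' Segment-averaged (direct FFT) estimator. For segments with spectra
#' `X_k(f)`, the bispectrum is `B(f1,f2) = E[X(f1) X(f2) conj(X(f1+f2))]`
#' and the squared bicoherence is
#' `b2(f1,f2) = |B|^2 / (E[|X(f1) X(f2)|^2] E[|X(f1+f2)|^2])`,
#' which approaches 1 under quadratic phase coupling and 0 for independent
#' phases. Estimates are returned on the square grid `0..nfft/2` for all
#' bifrequencies with `f1 + f2 <= nfft/2` (NA outside), which contains both
#' `(f1, f2)` and `(f2, f1)`.
#'
#' @param x numeric signal
#' @param nfft segment length (power of two)
#' @param overlap fractional segment overlap
#' @return list with `B` (complex matrix), `b2` (numeric matrix), `freqIdx`
#'   (0-based frequency bin indices), `nSegments`.
#' @export
bispectrumEstimate <- function(x, nfft = 128L, overlap = 0.5) {
  n <- length(x)
  step <- max(1L, as.integer(nfft * (1 - overlap)))
  starts <- seq(1L, n - nfft + 1L, by = step)
  if (length(starts) < 2L) stop("signal too short for bispectrum segments")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))
  half <- nfft %/% 2L
  grid <- expand.grid(i = 0:half, j = 0:half)
  grid <- grid[grid$i + grid$j <= half, ]
  i1 <- grid$i + 1L; i2 <- grid$j + 1L; i3 <- grid$i + grid$j + 1L
  accB <- complex(length(i1))
  acc12 <- numeric(length(i1)); acc3 <- numeric(length(i1))
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    X <- stats::fft((seg - mean(seg)) * w)
    t12 <- X[i1] * X[i2]
    accB <- accB + t12 * Conj(X[i3])
    acc12 <- acc12 + Mod(t12)^2
    acc3 <- acc3 + Mod(X[i3])^2
  }
  m <- length(starts)
  Bv <- accB / m
  b2v <- Mod(Bv)^2 / ((acc12 / m) * (acc3 / m) + 1e-30)
  B <- matrix(NA_complex_, half + 1L, half + 1L)
  b2 <- matrix(NA_real_, half + 1L, half + 1L)
  B[cbind(i1, i2)] <- Bv
  b2[cbind(i1, i2)] <- b2v
  list(B = B, b2 = b2, freqIdx = 0:half, nSegments = m)
}

#' Higher-order spectral features of one breath phase
#'
#' Summaries of the direct bispectrum over the principal bifrequency
#' region: mean and maximum bispectrum magnitude, normalized entropy of the
#' magnitude distribution, and mean squared bicoherence.
#'
#' @param x numeric phase signal
#' @param rate sampling rate (unused by the estimator, kept for a uniform
#'   feature-function signature)
#' @param nfft segment length
#' @param minSegments minimum number of segments required
#' @return Named numeric vector; all `NA` when too few segments fit.
#' @export
hosFeatures <- function(x, rate, nfft = 128L, minSegments = 8L) {
  nms <- c("hos_bisp_mean", "hos_bisp_max", "hos_bisp_entropy", "hos_bicoh_mean")
  nSeg <- max(0L, (length(x) - nfft) %/% (nfft %/% 2L) + 1L)
  if (nSeg < minSegments) return(stats::setNames(rep(NA_real_, length(nms)), nms))
  est <- bispectrumEstimate(x, nfft = nfft)
  mag <- Mod(est$B[!is.na(est$B)])
  p <- mag / sum(mag)
  stats::setNames(c(mean(mag), max(mag), entropyBits(p) / log2(length(p)),
                    mean(est$b2, na.rm = TRUE)), nms)
}
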
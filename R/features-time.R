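#' Higuchi fractal dimension
#'
#' @param x numeric series
#' @param kMax maximum scale
#' @return Fractal dimension (about 1 for smooth curves, about 2 for
#'   uncorrelated noise); `NA` for constant input.
#' @export
higuchiFd <- function(x, kMax = 8L) {
  n <- length(x)
  if (n < 2L * kMax || stats::sd(x) == 0) return(NA_real_)
  lk <- numeric(kMax)
  for (k in seq_len(kMax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) { lm[m] <- NA; next }
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / ((length(idx) - 1) * k) / k
    }
    lk[k] <- mean(lm, na.rm = TRUE)
  }
  stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(kMax))))[2]
}

#' Katz fractal dimension
#' @param x numeric series
#' @return Katz FD; `NA` for constant input.
#' @export
katzFd <- function(x) {
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  n <- length(x) - 1L
  L <- sum(sqrt(1 + diff(x)^2))
  d <- max(sqrt((seq_along(x) - 1)^2 + (x - x[1])^2))
  if (d == 0 || L == 0) return(NA_real_)
  log10(n) / (log10(n) + log10(d / L))
}

#' Time-domain features of one breath phase
#'
#' Higuchi and Katz fractal dimensions, zero-crossing rate (crossings per
#' sample; a tone of frequency f gives 2 f / rate), and amplitude-envelope
#' peak statistics (count, mean, SD of peak heights).
#'
#' @param x numeric phase signal
#' @param rate sampling rate in Hz (envelope window scaling)
#' @param kMax Higuchi maximum scale
#' @return Named numeric vector; fractal dimensions are `NA` for constant
#'   signals.
#' @export
timeFeatures <- function(x, rate = 16000, kMax = 8L) {
  nms <- c("td_higuchi", "td_katz", "td_zcr", "td_peak_count", "td_peak_mean", "td_peak_sd")
  if (!length(x)) return(stats::setNames(rep(NA_real_, length(nms)), nms))
  zcr <- sum(abs(diff(x >= 0))) / (length(x) - 1L)
  env <- movingRms(x, max(5L, round(0.02 * rate)))
  pk <- findEnvelopePeaks(env, 0.25 * max(env), max(3L, round(0.05 * rate)))
  stats::setNames(c(higuchiFd(x, kMax), katzFd(x), zcr,
                    length(pk),
                    if (length(pk)) mean(env[pk]) else NA_real_,
                    if (length(pk) > 1L) stats::sd(env[pk]) else NA_real_), nms)
}
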
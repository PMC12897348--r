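#' Cycle-perturbation features (jitter and shimmer)
#'
#' Detects cycle marks as amplitude-envelope peaks and computes local
#' jitter, `mean |T_i - T_{i+1}| / mean T`, over consecutive cycle periods
#' and local shimmer, `mean |A_i - A_{i+1}| / mean A`, over consecutive
#' peak amplitudes.
#'
#' @param x numeric waveform (whole recording or long phase)
#' @param rate sampling rate in Hz
#' @param minPeriodSec minimum separation between cycle marks (s)
#' @param heightFraction peak threshold as a fraction of the envelope max
#' @return Named vector `c(pt_jitter, pt_shimmer)`; `NA` when fewer than
#'   3 cycles are detected.
#' @export
perturbationFeatures <- function(x, rate, minPeriodSec = 0.5, heightFraction = 0.5) {
  nms <- c("pt_jitter", "pt_shimmer")
  env <- movingRms(x, max(5L, round(0.05 * rate)))
  pk <- findEnvelopePeaks(env, heightFraction * max(env), round(minPeriodSec * rate))
  if (length(pk) < 3L) return(stats::setNames(rep(NA_real_, 2L), nms))
  # refine each mark to the energy centroid of its burst: raw argmax peaks
  # wander on flat envelope plateaus, which would masquerade as jitter
  half <- round(minPeriodSec * rate / 2)
  marks <- vapply(pk, function(p) {
    ix <- max(1L, p - half):min(length(env), p + half)
    sum(ix * env[ix]^2) / sum(env[ix]^2)
  }, numeric(1))
  periods <- diff(marks) / rate
  amps <- env[pk]
  jit <- mean(abs(diff(periods))) / mean(periods)
  shm <- mean(abs(diff(amps))) / mean(amps)
  stats::setNames(c(jit, shm), nms)
}
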
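#' Zero-phase Butterworth band-pass filtering
#'
#' Applies a Butterworth band-pass forward and backward (zero phase), so the
#' effective magnitude response is the squared single-pass response and
#' breath onsets are not delayed. Defaults follow the analysis band for
#' tracheal breathing sounds: 75-3000 Hz, 4th order.
#'
#' @param recording a [BreathRecording-class]
#' @param low,high band edges in Hz
#' @param order filter order (per pass)
#' @return The filtered [BreathRecording-class] (same length).
#' @export
bandpassBreath <- function(recording, low = 75, high = 3000, order = 4) {
  rate <- recording@rate
  if (!(low > 0 && low < high && high < rate / 2))
    stop("band edges must satisfy 0 < low < high < rate/2")
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  y <- signal::filtfilt(bf, recording@samples)
  BreathRecording(as.numeric(y), rate, recording@route)
}

# Amplitude gain of the forward-backward Butterworth band-pass (the squared
# single-pass magnitude), from the analog prototype closed form.
butterBandpassGain2 <- function(f, low, high, order) {
  w <- 2 * pi * f; wl <- 2 * pi * low; wh <- 2 * pi * high
  # single-pass magnitude: |H| = 1/sqrt(1 + ((w^2 - wl*wh)/(w*(wh-wl)))^(2n))
  x <- (w^2 - wl * wh) / (w * (wh - wl))
  1 / (1 + x^(2 * order))
}

#' Breath-phase segmentation by windowed log-variance
#'
#' Computes the log of the sample variance in sliding windows, thresholds it
#' at `thresholdFraction` of the (max - min) log-variance range above the
#' minimum, merges active gaps shorter than `minPhaseMs`, drops active runs
#' shorter than `minPhaseMs`, and labels the surviving regions alternately
#' inspiration / expiration starting with inspiration (the recording
#' protocol begins with an inspiration).
#'
#' @param recording a band-passed [BreathRecording-class]
#' @param windowMs analysis window (ms)
#' @param overlapFraction window overlap in (0, 1)
#' @param thresholdFraction activity threshold as a fraction of the
#'   log-variance range
#' @param minPhaseMs minimum phase (and maximum mergeable gap) duration (ms)
#' @return A data.frame with columns `phase_index, kind, start_sample,
#'   end_sample` (0-based, half-open), or zero rows for silence.
#' @export
logvarSegment <- function(recording, windowMs = 50, overlapFraction = 0.5,
                          thresholdFraction = 0.25, minPhaseMs = 200) {
  stopifnot(overlapFraction > 0, overlapFraction < 1)
  x <- recording@samples; rate <- recording@rate
  win <- max(4L, round(windowMs / 1000 * rate))
  step <- max(1L, round(win * (1 - overlapFraction)))
  starts <- seq(1L, max(1L, length(x) - win + 1L), by = step)
  lv <- log(vapply(starts, function(s) stats::var(x[s:(s + win - 1L)]), numeric(1)) + 1e-20)
  rng <- max(lv) - min(lv)
  empty <- data.frame(phase_index = integer(0), kind = character(0),
                      start_sample = integer(0), end_sample = integer(0))
  if (rng < 1) {  # flat log-variance profile: silence
    warning("flat log-variance profile; no phases detected")
    return(empty)
  }
  active <- lv > min(lv) + thresholdFraction * rng
  # merge short inactive gaps
  minLen <- minPhaseMs / 1000 * rate
  r <- rle(active)
  pos <- cumsum(c(1L, r$lengths))
  for (i in seq_along(r$values)) {
    if (!r$values[i] && i > 1L && i < length(r$values) &&
        r$lengths[i] * step < minLen) r$values[i] <- TRUE
  }
  active <- inverse.rle(r)
  r <- rle(active)
  ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- list(); idx <- 0L
  for (j in keep) {
    s0 <- starts[begs[j]] - 1L                       # 0-based
    e0 <- min(length(x), starts[ends[j]] + win - 1L) # half-open end
    if ((e0 - s0) < minLen) next
    idx <- idx + 1L
    out[[idx]] <- data.frame(phase_index = idx,
                             kind = if (idx %% 2L == 1L) "inspiration" else "expiration",
                             start_sample = s0, end_sample = e0)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Spectral-subtraction denoising
#'
#' Estimates the noise magnitude spectrum from the quietest 10% of frames
#' (by frame energy) and subtracts it (with factor `beta`) from every frame
#' magnitude, flooring at 5% of the original magnitude, then resynthesizes
#' by overlap-add. When the estimated SNR already exceeds `snrThresholdDb`
#' the recording is returned unchanged.
#'
#' @param recording a [BreathRecording-class]
#' @param frameMs frame length (ms)
#' @param beta over-subtraction factor
#' @param snrThresholdDb SNR (dB) above which denoising is skipped
#' @return The denoised [BreathRecording-class].
#' @export
denoiseSpectral <- function(recording, frameMs = 32, beta = 1,
                            snrThresholdDb = 25) {
  x <- recording@samples; rate <- recording@rate
  nfft <- 2^ceiling(log2(frameMs / 1000 * rate))
  hop <- nfft %/% 2L
  if (length(x) < 4L * nfft) return(recording)
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / nfft)
  frames <- vapply(starts, function(s) x[s:(s + nfft - 1L)] * w, numeric(nfft))
  energy <- colSums(frames^2)
  qn <- stats::quantile(energy, 0.1)
  noiseFrames <- which(energy <= qn)
  snrDb <- 10 * log10(mean(energy) / (mean(energy[noiseFrames]) + 1e-30))
  if (snrDb > snrThresholdDb) return(recording)
  spec <- stats::mvfft(frames)
  noiseMag <- sqrt(rowMeans(Mod(spec[, noiseFrames, drop = FALSE])^2))
  mag <- Mod(spec)
  cleanMag <- pmax(mag - beta * noiseMag, 0.05 * mag)
  clean <- Re(stats::mvfft(cleanMag * exp(1i * Arg(spec)), inverse = TRUE)) / nfft
  y <- numeric(length(x)); norm <- numeric(length(x))
  for (k in seq_along(starts)) {
    s <- starts[k]
    y[s:(s + nfft - 1L)] <- y[s:(s + nfft - 1L)] + clean[, k] * w
    norm[s:(s + nfft - 1L)] <- norm[s:(s + nfft - 1L)] + w^2
  }
  # interior samples have window-squared coverage near 1; keep the original
  # signal where coverage is weak (global edges) to avoid amplification
  ok <- norm > 0.25
  y[ok] <- y[ok] / norm[ok]
  y[!ok] <- x[!ok]
  BreathRecording(y, rate, recording@route)
}
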
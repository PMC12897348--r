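# Internal helpers: seeded RNG streams, envelopes, Welch PSD, peak picking.

# Derive a reproducible child seed from a base seed and one or more indices.
# Kept below 2^31 so it is always a valid R integer seed.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 69069 + as.double(k) * 104729 + 1) %% 2147483647
  as.integer(s)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Moving-RMS amplitude envelope (window in samples).
movingRms <- function(x, win) {
  win <- max(3L, as.integer(win))
  cs <- cumsum(c(0, x^2))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - win %/% 2L - 1L)
  hi <- pmin(n, seq_len(n) + win %/% 2L)
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

# Welch power spectral density with Hann windows.
# Returns list(freq, psd) with one-sided density (arbitrary consistent scale).
welchPsd <- function(x, rate, nfft = 256L, overlap = 0.5) {
  n <- length(x)
  nfft <- min(nfft, n)
  step <- max(1L, as.integer(nfft * (1 - overlap)))
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))
  u <- sum(w^2)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * w
    X <- stats::fft(seg)
    p <- Mod(X[seq_len(nfft %/% 2L + 1L)])^2 / (u * rate)
    p[2:(nfft %/% 2L)] <- 2 * p[2:(nfft %/% 2L)]
    acc <- acc + p
  }
  list(freq = (0:(nfft %/% 2L)) * rate / nfft, psd = acc / length(starts))
}

# Local-maxima peak picker with minimum height and minimum separation.
findEnvelopePeaks <- function(env, minHeight, minDist) {
  n <- length(env)
  if (n < 3L) return(integer(0))
  cand <- which(env[2:(n - 1L)] >= env[1:(n - 2L)] &
                env[2:(n - 1L)] > env[3:n] &
                env[2:(n - 1L)] >= minHeight) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(env[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand) {
    if (!length(keep) || all(abs(keep - p) >= minDist)) keep <- c(keep, p)
  }
  sort(keep)
}

# Shannon entropy (bits) of a probability vector; zero-mass bins ignored.
entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Standardize columns with given (or computed) centers/scales; zero scales pass through.
scaleCols <- function(m, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(m)
  if (is.null(scale)) scale <- apply(m, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  sweep(sweep(m, 2, center, "-"), 2, scale, "/")
}

balancedAccuracy <- function(pred, truth) {
  lev <- unique(truth)
  mean(vapply(lev, function(l) mean(pred[truth == l] == l), numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
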
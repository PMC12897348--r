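# Time-delay embedding: rows are state vectors.
.embed <- function(x, dim, delay) {
  n <- length(x) - (dim - 1L) * delay
  if (n < 2L) return(NULL)
  sapply(seq_len(dim), function(d) x[(1:n) + (d - 1L) * delay])
}

# First zero crossing of the autocorrelation (capped), default embedding delay.
.acfZeroDelay <- function(x, cap = NULL) {
  cap <- cap %||% max(2L, length(x) %/% 10L)
  a <- stats::acf(x, lag.max = cap, plot = FALSE)$acf[-1]
  z <- which(a <= 0)[1]
  if (is.na(z)) cap else max(1L, z)
}

#' Recurrence quantification analysis
#'
#' RQA of a time-delay embedding with a fixed-radius threshold chosen as
#' the distance quantile that achieves the target recurrence rate.
#' Reports recurrence rate, determinism (fraction of recurrent points on
#' diagonal lines of length >= `lMin`), laminarity (vertical lines), and
#' the longest diagonal line off the identity.
#'
#' @param x numeric series (already downsampled as appropriate)
#' @param dim embedding dimension
#' @param delay embedding delay; default first autocorrelation zero
#' @param targetRate target recurrence rate for the radius rule
#' @param lMin minimum line length
#' @return Named list; `NULL` for degenerate (constant) input.
#' @export
rqa <- function(x, dim = 3L, delay = NULL, targetRate = 0.1, lMin = 2L) {
  if (stats::sd(x) == 0) return(NULL)
  delay <- delay %||% .acfZeroDelay(x)
  E <- .embed(x, dim, delay)
  if (is.null(E) || nrow(E) < 10L) return(NULL)
  D <- as.matrix(stats::dist(E))
  n <- nrow(D)
  off <- D[upper.tri(D)]
  eps <- stats::quantile(off, targetRate, names = FALSE)
  R <- D <= eps
  diag(R) <- FALSE
  nRec <- sum(R)
  if (nRec == 0) return(list(rr = 0, det = NA_real_, lam = NA_real_, lmax = 0))
  diagPts <- 0L; lmax <- 0L
  for (k in seq_len(n - 1L)) {
    d <- R[cbind(1:(n - k), (1 + k):n)]
    r <- rle(d)
    runs <- r$lengths[r$values]
    if (length(runs)) {
      diagPts <- diagPts + sum(runs[runs >= lMin])
      lmax <- max(lmax, max(runs))
    }
  }
  vertPts <- 0L
  for (j in seq_len(n)) {
    r <- rle(R[, j])
    runs <- r$lengths[r$values]
    if (length(runs)) vertPts <- vertPts + sum(runs[runs >= lMin])
  }
  list(rr = nRec / (n * (n - 1L)),
       det = 2 * diagPts / nRec,   # both triangles
       lam = vertPts / nRec,
       lmax = lmax)
}

#' Largest Lyapunov exponent (Rosenstein's method)
#'
#' Mean log divergence of initially nearest trajectories (with a temporal
#' exclusion window), with the exponent taken as the slope of the
#' divergence curve over the first `kMax` steps, in nats per sample.
#'
#' @param x numeric series
#' @param dim embedding dimension
#' @param delay embedding delay; default first autocorrelation zero
#' @param kMax divergence horizon in steps
#' @return Slope estimate, or `NA` for degenerate input.
#' @export
lyapunovRosenstein <- function(x, dim = 3L, delay = NULL, kMax = 20L) {
  if (stats::sd(x) == 0) return(NA_real_)
  delay <- delay %||% .acfZeroDelay(x)
  E <- .embed(x, dim, delay)
  if (is.null(E) || nrow(E) < 4L * kMax) return(NA_real_)
  n <- nrow(E)
  D <- as.matrix(stats::dist(E))
  theiler <- max(delay, 2L)
  for (i in seq_len(n)) {
    lo <- max(1L, i - theiler); hi <- min(n, i + theiler)
    D[i, lo:hi] <- Inf
  }
  nn <- max.col(-D[seq_len(n - kMax), seq_len(n - kMax), drop = FALSE],
                ties.method = "first")
  # divergence curve from k = 0 (initial neighbour distance) so the rapid
  # first-step separation of stochastic signals is captured
  ks <- 0:kMax
  div <- vapply(ks, function(k) {
    i <- seq_len(n - kMax)
    d <- sqrt(rowSums((E[i + k, , drop = FALSE] - E[nn + k, , drop = FALSE])^2))
    mean(log(d[d > 0]))
  }, numeric(1))
  unname(stats::coef(stats::lm(div ~ ks))[2])
}

#' Nonlinear-dynamics features of one breath phase
#'
#' RQA measures and the largest Lyapunov exponent computed on the phase
#' signal decimated to at most `maxPoints` samples.
#'
#' @param x numeric phase signal (>= 500 samples before decimation)
#' @param maxPoints decimation target
#' @return Named numeric vector; all `NA` for too-short or constant input.
#' @export
nonlinearFeatures <- function(x, maxPoints = 300L) {
  nms <- c("nl_rr", "nl_det", "nl_lam", "nl_lmax", "nl_lyap")
  if (length(x) < 500L || stats::sd(x) == 0)
    return(stats::setNames(rep(NA_real_, length(nms)), nms))
  if (length(x) > maxPoints) x <- x[seq(1L, length(x), by = ceiling(length(x) / maxPoints))]
  delay <- .acfZeroDelay(x)
  r <- rqa(x, delay = delay)
  ly <- lyapunovRosenstein(x, delay = delay)
  if (is.null(r)) return(stats::setNames(rep(NA_real_, length(nms)), nms))
  stats::setNames(c(r$rr, r$det, r$lam, r$lmax / length(x), ly), nms)
}
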
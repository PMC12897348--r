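# Default per-class population parameters for the synthetic cohort generator.
# Continuous fields are mean/SD targets for truncated sampling; sex is the
# male proportion; MPS is a 4-level probability vector. These defaults emulate
# the reference clinical population the package is designed around.
.defaultAnthro <- function() {
  list(
    non      = list(ahi = c(1.18, 1.26),  age = c(46.84, 12.89), sex_m = 29 / 74,
                    bmi = c(30.61, 6.29), mps = c(41, 19, 6, 8) / 74,  nc = c(38.78, 4.04)),
    # mild MPS counts total 34 of 35 subjects (one unscored); normalized by the
    # category total so the probabilities sum to 1
    mild     = list(ahi = c(8.69, 2.58),  age = c(52.31, 11.57), sex_m = 21 / 35,
                    bmi = c(34.29, 8.41), mps = c(18, 6, 9, 1) / 34,   nc = c(42.09, 6.49)),
    moderate = list(ahi = c(21.51, 4.23), age = c(54.74, 11.33), sex_m = 36 / 50,
                    bmi = c(33.78, 6.39), mps = c(17, 17, 8, 8) / 50,  nc = c(43.10, 3.43)),
    severe   = list(ahi = c(69.54, 33.26), age = c(48.98, 11.15), sex_m = 30 / 40,
                    bmi = c(39.75, 8.65), mps = c(5, 13, 14, 8) / 40,  nc = c(45.28, 3.64))
  )
}

# AHI class intervals used for truncated sampling (severe capped at 150).
.ahiIntervals <- function() {
  list(non = c(0, 5), mild = c(5, 15), moderate = c(15, 30), severe = c(30, 150))
}

# Physiologic truncation bounds for continuous anthropometrics.
.anthroBounds <- function() {
  list(age = c(18, 90), bmi = c(15, 60), nc = c(25, 60))
}

#' Specification of a synthetic cohort
#'
#' Bundles everything the generator needs: per-class subject counts,
#' per-class anthropometric distribution parameters, the acoustic effect
#' size controlling between-class spectral separation, the anthropometric
#' missingness rate, the recording protocol (sampling rate, breath cycles
#' per route), and the master seed.
#'
#' @param classSizes named integer vector over the severity classes;
#'   defaults to the reference cohort sizes (74, 35, 50, 40).
#' @param anthro per-class distribution parameters; defaults emulate the
#'   reference population (see package vignette).
#' @param acousticEffectSize non-negative scalar; 0 makes all classes
#'   acoustically identical in distribution.
#' @param missingRate MCAR missingness fraction for anthropometrics, in [0, 1).
#' @param rate audio sampling rate in Hz.
#' @param cycles deep-breath cycles per route recording.
#' @param seed master integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohortSpec <- function(classSizes = c(non = 74, mild = 35, moderate = 50, severe = 40),
                       anthro = .defaultAnthro(),
                       acousticEffectSize = 1,
                       missingRate = 0,
                       rate = 16000,
                       cycles = 5,
                       seed = 1) {
  stopifnot(all(severityLevels() %in% names(classSizes)),
            all(classSizes >= 0),
            acousticEffectSize >= 0,
            missingRate >= 0, missingRate < 1,
            rate > 6000, cycles >= 1)
  for (cl in severityLevels()) {
    p <- anthro[[cl]]$mps
    if (abs(sum(p) - 1) > 1e-8) stop("MPS probabilities must sum to 1 for class ", cl)
    if (anthro[[cl]]$sex_m < 0 || anthro[[cl]]$sex_m > 1) stop("sex proportion out of [0,1]")
  }
  structure(list(classSizes = classSizes[severityLevels()], anthro = anthro,
                 acousticEffectSize = acousticEffectSize, missingRate = missingRate,
                 rate = rate, cycles = cycles, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Truncated normal sampling by inverse-CDF, n draws. The underlying mean is
# adjusted so the post-truncation mean hits `mean` exactly (truncation at
# physiologic bounds would otherwise bias class means away from their
# population targets).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  truncMean <- function(mu) {
    a <- (lower - mu) / sd; b <- (upper - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  mu <- tryCatch(stats::uniroot(function(m) truncMean(m) - mean,
                                c(mean - 3 * sd, mean + 3 * sd))$root,
                 error = function(e) mean)
  lo <- stats::pnorm(lower, mu, sd)
  hi <- stats::pnorm(upper, mu, sd)
  stats::qnorm(stats::runif(n, lo, hi), mu, sd)
}

# Truncated log-normal with moment-matched (mean, sd), truncated to [lower, upper].
rtrunclnorm <- function(n, mean, sd, lower, upper) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  lo <- stats::plnorm(max(lower, 1e-9), meanlog, sdlog)
  hi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}
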
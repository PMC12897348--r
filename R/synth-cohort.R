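#' Synthesize one deep-breathing recording
#'
#' Builds a waveform of `cycles` breath cycles (1.2 s inspiration, 1.6 s
#' expiration, 0.4 s pause), each an amplitude-enveloped burst of pink-ish
#' noise shaped by two resonances. The resonance centers and the spectral
#' tilt shift linearly with the severity index scaled by `effectSize`, so
#' that `effectSize = 0` makes all classes acoustically identical in
#' distribution. Low-level white sensor noise is added throughout.
#'
#' @param severity severity label (see [severityLevels()])
#' @param route `"nose"` or `"mouth"`
#' @param effectSize non-negative separation scale
#' @param seed integer seed
#' @param rate sampling rate in Hz
#' @param cycles number of breath cycles
#' @return A [BreathRecording-class].
#' @export
synthBreathRecording <- function(severity, route = c("nose", "mouth"),
                                 effectSize = 1, seed = 1,
                                 rate = 16000, cycles = 5) {
  route <- match.arg(route)
  stopifnot(effectSize >= 0, severity %in% severityLevels())
  sev <- match(severity, severityLevels()) - 1L
  withSeed(seed, {
    # cycle: inspiration, short post-inspiratory gap (lets the segmenter
    # separate the phases), expiration, inter-cycle pause
    tIns <- 1.2; tGap <- 0.3; tExp <- 1.6; tPau <- 0.4
    nIns <- round(tIns * rate); nGap <- round(tGap * rate)
    nExp <- round(tExp * rate); nPau <- round(tPau * rate)
    nCyc <- nIns + nGap + nExp + nPau
    n <- cycles * nCyc
    # class- and route-dependent resonances (Hz) and tilt
    f1 <- 420 + 55 * sev * effectSize + if (route == "mouth") 35 else 0
    f2 <- 1150 + 85 * sev * effectSize + if (route == "mouth") 90 else 0
    tilt <- 0.55 + 0.06 * sev * effectSize      # one-pole low-pass pole radius
    shapeNoise <- function(m, ampJit) {
      w <- stats::rnorm(m)
      pinkish <- as.numeric(signal::filter(c(1), c(1, -tilt), w))
      res <- function(x, fc, bw) {
        r <- exp(-pi * bw / rate)
        th <- 2 * pi * fc / rate
        as.numeric(signal::filter(c(1 - r), c(1, -2 * r * cos(th), r^2), x))
      }
      y <- 0.7 * res(pinkish, f1, 150) + 0.5 * res(pinkish, f2, 250)
      ampJit * y / (stats::sd(y) + 1e-12)
    }
    hann <- function(m) 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))
    x <- numeric(n)
    for (c in seq_len(cycles)) {
      off <- (c - 1L) * nCyc
      aIns <- 1.0 * (1 + 0.05 * stats::rnorm(1))
      aExp <- 0.72 * (1 + 0.05 * stats::rnorm(1))
      x[off + seq_len(nIns)] <- shapeNoise(nIns, aIns) * hann(nIns)
      x[off + nIns + nGap + seq_len(nExp)] <- shapeNoise(nExp, aExp) * hann(nExp)
    }
    x <- x + 0.004 * stats::rnorm(n)
    BreathRecording(0.25 * x, rate, route)
  })
}

#' Count breath cycles from the amplitude envelope
#'
#' Detects inspiratory bursts as envelope peaks at least 70% of the cycle
#' period apart and above 60% of the maximum envelope.
#'
#' @param recording a [BreathRecording-class]
#' @return Integer number of detected cycles.
#' @export
countBreathCycles <- function(recording) {
  env <- movingRms(recording@samples, round(0.1 * recording@rate))
  pk <- findEnvelopePeaks(env, 0.6 * max(env), round(0.7 * 3.5 * recording@rate))
  length(pk)
}

#' Generate a synthetic cohort
#'
#' Draws per-class subject counts exactly equal to the specification, with
#' AHI from a truncated log-normal matched to the class mean/SD and
#' truncated to the class interval, continuous anthropometrics from
#' truncated normals at physiologic bounds, sex and Mallampati score from
#' per-class category probabilities, and (optionally) one nose and one
#' mouth deep-breathing recording per subject. Each subject owns an RNG
#' stream derived from `(seed, class, index)` so cohorts are stable under
#' class-size edits.
#'
#' @param spec a [cohortSpec()]
#' @param audio logical; generate waveforms (set `FALSE` for fast
#'   anthropometrics-only cohorts, e.g. distributional checks)
#' @return A [SoundCohort-class].
#' @export
generateCohort <- function(spec = cohortSpec(), audio = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$classSizes == 0))
    warning("some class has zero subjects; downstream stratification will be limited")
  iv <- .ahiIntervals(); bd <- .anthroBounds()
  rows <- list(); recs <- list()
  for (ci in seq_along(severityLevels())) {
    cl <- severityLevels()[ci]
    nC <- spec$classSizes[[cl]]
    if (nC == 0) next
    pars <- spec$anthro[[cl]]
    for (i in seq_len(nC)) {
      sid <- sprintf("%s_%03d", cl, i)
      s <- deriveSeed(spec$seed, ci, i)
      vals <- withSeed(s, {
        list(
          ahi = rtrunclnorm(1, pars$ahi[1], pars$ahi[2], iv[[cl]][1], iv[[cl]][2]),
          age = rtruncnorm(1, pars$age[1], pars$age[2], bd$age[1], bd$age[2]),
          sex = if (stats::runif(1) < pars$sex_m) "M" else "F",
          bmi = rtruncnorm(1, pars$bmi[1], pars$bmi[2], bd$bmi[1], bd$bmi[2]),
          nc  = rtruncnorm(1, pars$nc[1],  pars$nc[2],  bd$nc[1],  bd$nc[2]),
          mps = sample.int(4L, 1L, prob = pars$mps)
        )
      })
      rows[[sid]] <- data.frame(subject_id = sid, ahi = vals$ahi,
                                severity = severityFromAhi(vals$ahi),
                                age = vals$age, sex = vals$sex, bmi = vals$bmi,
                                nc = vals$nc, mps = vals$mps)
      if (audio) {
        recs[[sid]] <- list(
          nose = synthBreathRecording(cl, "nose", spec$acousticEffectSize,
                                      deriveSeed(s, 1L), spec$rate, spec$cycles),
          mouth = synthBreathRecording(cl, "mouth", spec$acousticEffectSize,
                                       deriveSeed(s, 2L), spec$rate, spec$cycles)
        )
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("SoundCohort", subjects = DataFrame(tab), recordings = recs,
      spec = unclass(spec))
}

#' Inject MCAR missingness into anthropometric features
#'
#' Masks each anthropometric cell independently with probability `rate`
#' (missing completely at random). Acoustic features and the severity label
#' are never masked.
#'
#' @param table a [FeatureTable-class]
#' @param rate missingness fraction in [0, 1)
#' @param seed integer seed; the mask is a deterministic function of it
#' @return The table with masked cells set to `NA` and flagged.
#' @export
injectMissingness <- function(table, rate, seed = 1) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(table)
  eligible <- which(featureFamily(table) == "anthropometric")
  v <- featureValues(table); m <- missingMask(table)
  hit <- withSeed(seed, matrix(stats::runif(length(eligible) * ncol(v)) < rate,
                               nrow = length(eligible)))
  v[eligible, ][hit] <- NA
  m[eligible, ][hit] <- TRUE
  SummarizedExperiment::assay(table, "values") <- v
  SummarizedExperiment::assay(table, "mask") <- m
  table
}

#' Simulate a feature-level cohort
#'
#' Generates a [FeatureTable-class] directly in feature space: real
#' anthropometrics from the same per-class population parameters as
#' [generateCohort()], plus Gaussian acoustic-style features whose means
#' shift linearly with the severity index scaled by `effectSize` (a random
#' direction per informative feature). This is the desk-scale route for
#' large Monte Carlo studies (e.g. conformal coverage), where only the
#' exchangeability and class structure of the rows matter, not acoustic
#' realism; the audio route via [generateCohort()] + [extractFeatures()]
#' exercises the full signal pipeline.
#'
#' @param classSizes named counts per severity class
#' @param effectSize between-class mean separation (in within-class SD units
#'   per severity step, spread over informative features)
#' @param nFeatures number of acoustic-style features
#' @param informativeFraction fraction of acoustic features carrying signal
#' @param seed integer seed
#' @param anthro per-class anthropometric parameters
#' @return A [FeatureTable-class] (no missingness; add with
#'   [injectMissingness()]).
#' @export
simulateFeatureCohort <- function(classSizes = c(non = 30, mild = 30, moderate = 30, severe = 30),
                                  effectSize = 1, nFeatures = 24,
                                  informativeFraction = 0.5, seed = 1,
                                  anthro = .defaultAnthro()) {
  stopifnot(all(severityLevels() %in% names(classSizes)), effectSize >= 0)
  iv <- .ahiIntervals(); bd <- .anthroBounds()
  nInf <- max(1L, round(informativeFraction * nFeatures))
  withSeed(seed, {
    dirs <- matrix(0, nFeatures, 1)
    dirs[seq_len(nInf), 1] <- stats::rnorm(nInf)
    dirs <- dirs / sqrt(sum(dirs^2)) * sqrt(nInf)
    sevAll <- rep(severityLevels(), times = classSizes[severityLevels()])
    n <- length(sevAll)
    sevIdx <- match(sevAll, severityLevels()) - 1L
    ac <- matrix(stats::rnorm(n * nFeatures), nFeatures, n) +
      outer(dirs[, 1], sevIdx * effectSize / 3)
    an <- sapply(seq_len(n), function(i) {
      pars <- anthro[[sevAll[i]]]
      c(age = rtruncnorm(1, pars$age[1], pars$age[2], bd$age[1], bd$age[2]),
        sex = as.numeric(stats::runif(1) < pars$sex_m),
        bmi = rtruncnorm(1, pars$bmi[1], pars$bmi[2], bd$bmi[1], bd$bmi[2]),
        nc  = rtruncnorm(1, pars$nc[1], pars$nc[2], bd$nc[1], bd$nc[2]),
        mps = sample.int(4L, 1L, prob = pars$mps))
    })
    values <- rbind(ac, an)
    rownames(values) <- c(sprintf("acoustic_%03d", seq_len(nFeatures)),
                          c("age", "sex", "bmi", "nc", "mps"))
    colnames(values) <- sprintf("s%03d", seq_len(n))
    fam <- c(rep(c("spectral", "hos", "time", "tf", "nonlinear"), length.out = nFeatures),
             rep("anthropometric", 5))
    FeatureTable(values, family = fam, severity = sevAll)
  })
}
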
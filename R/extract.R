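#' Extract all feature families from one breath phase
#'
#' @param x numeric phase signal
#' @param rate sampling rate in Hz
#' @param config optional parameter overrides (list with any of
#'   `welch_nfft`, `hos_nfft`, `higuchi_kmax`, `nl_max_points`)
#' @return Named numeric vector over the per-phase feature dictionary;
#'   failed families are `NA` (explicit missing), never silent NaN.
#' @export
phaseFeatures <- function(x, rate, config = list()) {
  out <- c(spectralFeatures(x, rate, nfft = config$welch_nfft %||% 256L),
           hosFeatures(x, rate, nfft = config$hos_nfft %||% 128L),
           timeFeatures(x, rate, kMax = config$higuchi_kmax %||% 8L),
           tfFeatures(x, rate),
           nonlinearFeatures(x, maxPoints = config$nl_max_points %||% 300L))
  out[is.nan(out)] <- NA
  out
}

#' Aggregate per-phase feature vectors
#'
#' Element-wise mean over phases with missing values ignored per feature;
#' a feature missing in every phase stays missing.
#'
#' @param phaseVectors list of equally named numeric vectors
#' @return Named numeric vector.
#' @export
aggregateSubject <- function(phaseVectors) {
  stopifnot(length(phaseVectors) >= 1L)
  m <- do.call(rbind, phaseVectors)
  out <- colMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA
  out
}

# Per-subject acoustic vector: phase extraction per route recording, mean
# aggregation split by route x phase kind, plus route-level perturbation.
.subjectAcoustics <- function(recs, config = list(), denoise = TRUE) {
  out <- c()
  for (route in c("nose", "mouth")) {
    rec <- recs[[route]]
    if (denoise) rec <- denoiseSpectral(rec)
    bp <- bandpassBreath(rec,
                         low = config$band_low %||% 75,
                         high = min(config$band_high %||% 3000, rec@rate / 2 - 1),
                         order = config$band_order %||% 4)
    ph <- suppressWarnings(logvarSegment(bp))
    for (kind in c("inspiration", "expiration")) {
      sel <- ph[ph$kind == kind, , drop = FALSE]
      vecs <- lapply(seq_len(nrow(sel)), function(i)
        phaseFeatures(bp@samples[(sel$start_sample[i] + 1L):sel$end_sample[i]],
                      bp@rate, config))
      agg <- if (length(vecs)) aggregateSubject(vecs)
             else phaseFeatures(numeric(0), bp@rate, config)  # all-missing template
      pre <- paste0(route, "_", if (kind == "inspiration") "insp" else "exp", "_")
      names(agg) <- paste0(pre, names(agg))
      out <- c(out, agg)
    }
    pt <- perturbationFeatures(bp@samples, bp@rate,
                               minPeriodSec = config$pt_min_period %||% 2.0,
                               heightFraction = config$pt_height %||% 0.5)
    names(pt) <- paste0(route, "_", names(pt))
    out <- c(out, pt)
  }
  out
}

#' Extract the feature table for a cohort
#'
#' Runs denoising, band-pass filtering, breath-phase segmentation, and the
#' full per-phase feature dictionary for every recording, aggregates
#' phase-level vectors to one vector per subject (separately for
#' nose/mouth and inspiration/expiration, giving route-and-phase prefixed
#' names), and appends the five anthropometric features (age, sex, BMI,
#' NC, MPS; sex coded M=1/F=0).
#'
#' @param cohort a [SoundCohort-class] with audio
#' @param config optional list of extraction parameter overrides
#' @param denoise apply spectral-subtraction denoising first
#' @return A [FeatureTable-class] (features x subjects) with feature-family
#'   metadata and `metadata(x)$extraction` recording the dictionary version
#'   and parameters.
#' @export
extractFeatures <- function(cohort, config = list(), denoise = TRUE) {
  tab <- subjectTable(cohort)
  if (!length(cohort@recordings)) stop("cohort has no audio; generate with audio = TRUE")
  vecs <- lapply(tab$subject_id, function(sid)
    .subjectAcoustics(subjectRecordings(cohort, sid), config, denoise))
  values <- do.call(cbind, vecs)
  colnames(values) <- tab$subject_id
  anthro <- rbind(age = tab$age, sex = as.numeric(tab$sex == "M"),
                  bmi = tab$bmi, nc = tab$nc, mps = as.numeric(tab$mps))
  colnames(anthro) <- tab$subject_id
  fam <- vapply(rownames(values), function(nm) {
    base <- sub("^(nose|mouth)_", "", sub("^(nose|mouth)_(insp|exp)_", "", nm))
    switch(substr(base, 1, 3),
           sp_ = "spectral", hos = "hos", td_ = "time",
           tf_ = "tf", nl_ = "nonlinear", pt_ = "perturbation", "acoustic")
  }, character(1))
  ft <- FeatureTable(rbind(values, anthro),
                     family = c(fam, rep("anthropometric", 5L)),
                     severity = tab$severity,
                     colData = tab[, c("subject_id", "ahi", "age", "sex", "bmi", "nc", "mps")])
  metadata(ft)$extraction <- list(dictionary_version = "1.0",
                                  config = config, denoise = denoise)
  ft
}
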
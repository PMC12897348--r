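#' Stratified calibration split
#'
#' Holds out a class-stratified fraction of the training rows for conformal
#' calibration; per class the calibration count is `round(holdout * n_c)`
#' (half rounded up). Fit and calibration sets are disjoint and exhaustive.
#'
#' @param labels scheme class labels of the training rows
#' @param holdout calibration fraction in (0, 1), default 0.2
#' @param seed integer seed
#' @return List with integer index vectors `fit` and `calib` (positions in
#'   `labels`).
#' @export
calibrationSplit <- function(labels, holdout = 0.2, seed = 1L) {
  stopifnot(holdout > 0, holdout < 1)
  calib <- integer(0)
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    nCal <- floor(holdout * length(ix) + 0.5)
    if (nCal == 0L)
      warning("class '", cl, "' absent from calibration split")
    if (nCal > 0L)
      calib <- c(calib, withSeed(deriveSeed(seed, match(cl, unique(labels))),
                                 sample(ix, nCal)))
  }
  calib <- sort(calib)
  list(fit = setdiff(seq_along(labels), calib), calib = calib)
}

#' Nonconformity score
#'
#' The strangeness of a label for an input: one minus its estimated class
#' probability, `s(x, y) = 1 - p(y | x)`.
#'
#' @param prob probability (vector or matrix) in [0, 1]
#' @return `1 - prob`.
#' @export
nonconformity <- function(prob) {
  stopifnot(all(prob >= 0 & prob <= 1))
  1 - prob
}

#' Split-conformal quantile threshold
#'
#' The `ceiling((1 - alpha) (n + 1))`-th smallest element of the
#' calibration scores augmented with infinity; when that rank exceeds `n`
#' the threshold is `Inf`. This finite-sample convention yields marginal
#' coverage at least `1 - alpha` under exchangeability.
#'
#' @param calibScores calibration nonconformity scores
#' @param alpha significance level in (0, 1)
#' @return A [ConformalCalibration-class].
#' @export
fitThreshold <- function(calibScores, alpha) {
  stopifnot(length(calibScores) >= 1L, alpha > 0, alpha < 1)
  n <- length(calibScores)
  k <- ceiling((1 - alpha) * (n + 1))
  q <- if (k > n) Inf else sort(calibScores)[k]
  new("ConformalCalibration", alpha = alpha,
      calibScores = as.numeric(calibScores), qHat = q, nCalib = as.integer(n))
}

#' Conformal prediction sets
#'
#' Includes every label whose nonconformity `1 - p(y | x)` is at most the
#' calibrated threshold. Sets may be empty (when every score exceeds the
#' threshold); empty sets are kept and count as misses in coverage, which
#' preserves the guarantee.
#'
#' @param probs probability matrix, subjects x classes (named columns)
#' @param calibration a [ConformalCalibration-class] (or a numeric `qHat`)
#' @return A [ConformalSets-class].
#' @export
predictSets <- function(probs, calibration) {
  q <- if (is(calibration, "ConformalCalibration")) calibration@qHat else calibration
  s <- 1 - probs
  new("ConformalSets", membership = s <= q, scores = s, qUsed = q)
}

#' Empirical coverage of prediction sets
#'
#' The proportion of subjects whose true label is contained in their
#' prediction set.
#'
#' @param sets a [ConformalSets-class]
#' @param truths true class labels (aligned with the set rows)
#' @return Coverage fraction in [0, 1].
#' @export
coverage <- function(sets, truths) {
  if (length(truths) != nrow(sets@membership)) stop("length mismatch")
  mean(sets@membership[cbind(seq_along(truths),
                             match(truths, colnames(sets@membership)))])
}

#' Average prediction-set size
#'
#' Mean number of labels per set; smaller is more efficient at equal
#' coverage.
#'
#' @param sets a [ConformalSets-class]
#' @return Mean set size.
#' @export
avgSetSize <- function(sets) {
  stopifnot(nrow(sets@membership) > 0L)
  mean(rowSums(sets@membership))
}

#' Monte Carlo study of marginal conformal coverage
#'
#' Repeats, with fresh seeds: draw a synthetic four-class feature-level
#' cohort, split off a stratified test set, hold out a stratified
#' calibration set from the remaining training rows, train the one-vs-one
#' bundle on the fit rows and the stacked meta-model on their out-of-bag
#' scores, calibrate the conformal threshold on the calibration rows, and
#' record the empirical test coverage. Calibration and test rows are
#' exchangeable by construction, so mean coverage must be at least
#' `1 - alpha` up to Monte Carlo error.
#'
#' @param nReps number of independent repetitions
#' @param classSizes cohort class sizes per repetition
#' @param alpha conformal significance level
#' @param effectSize cohort separability
#' @param testFraction held-out test fraction
#' @param holdout calibration fraction of the training rows
#' @param candidates,metaCandidates,B base/meta learner settings (lean
#'   defaults sized for repetition)
#' @param seed master seed
#' @return List with `coverages` (per repetition), `meanCoverage`,
#'   `mcse` (Monte Carlo standard error), `avgSetSizes`.
#' @export
conformalCoverageStudy <- function(nReps = 500L,
                                   classSizes = c(non = 45, mild = 21, moderate = 30, severe = 24),
                                   alpha = 0.05, effectSize = 1,
                                   testFraction = 0.15, holdout = 0.2,
                                   candidates = "logistic",
                                   metaCandidates = "multinomial",
                                   B = 10L, seed = 1L) {
  cov <- numeric(nReps); sz <- numeric(nReps)
  for (r in seq_len(nReps)) {
    s <- deriveSeed(seed, r)
    tab <- simulateFeatureCohort(classSizes, effectSize = effectSize,
                                 nFeatures = 16L, seed = s)
    sev <- severityLabels(tab)
    sp <- stratifiedSplit(subjectTableFromFeatures(tab), testFraction,
                          seed = deriveSeed(s, 2L), swaps = 0L)
    fitRes <- fitOsaPipeline(tab, scheme = "four", trainIdx = sp$train,
                             alpha = alpha, holdout = holdout,
                             impute = FALSE, normalize = FALSE, select = FALSE,
                             candidates = candidates,
                             metaCandidates = metaCandidates,
                             B = B, budget = 1L, seed = deriveSeed(s, 3L))
    pred <- predictPipeline(fitRes, tab, sp$test)
    cov[r] <- coverage(pred$sets, applyScheme(sev[sp$test], fitRes$scheme))
    sz[r] <- avgSetSize(pred$sets)
  }
  list(coverages = cov, meanCoverage = mean(cov),
       mcse = stats::sd(cov) / sqrt(nReps), avgSetSizes = sz)
}
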
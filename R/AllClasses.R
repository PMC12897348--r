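#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Severity class labels
#'
#' Ordered labels for the four apnea-hypopnea-index (AHI) severity classes
#' used throughout the package.
#'
#' @return Character vector `c("non", "mild", "moderate", "severe")`.
#' @export
severityLevels <- function() c("non", "mild", "moderate", "severe")

#' BreathRecording: a single-route breathing-sound recording
#'
#' Holds a mono waveform of deep breathing recorded over the suprasternal
#' notch through one route (nose or mouth), with its sampling rate.
#'
#' @slot samples Numeric waveform (finite values).
#' @slot rate Sampling rate in Hz.
#' @slot route Either `"nose"` or `"mouth"`.
#' @export
setClass("BreathRecording",
  representation(samples = "numeric", rate = "numeric", route = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@samples) == 0L) msg <- c(msg, "empty waveform")
    if (any(!is.finite(object@samples))) msg <- c(msg, "non-finite samples")
    if (length(object@rate) != 1L || object@rate <= 0) msg <- c(msg, "rate must be a positive scalar")
    if (!object@route %in% c("nose", "mouth")) msg <- c(msg, "route must be 'nose' or 'mouth'")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a BreathRecording
#' @param samples numeric waveform
#' @param rate sampling rate (Hz)
#' @param route `"nose"` or `"mouth"`
#' @return A [BreathRecording-class] object.
#' @export
BreathRecording <- function(samples, rate, route = "nose") {
  new("BreathRecording", samples = as.numeric(samples), rate = rate, route = route)
}

#' @describeIn BreathRecording-class recording duration in seconds
#' @param x a BreathRecording
#' @export
recordingDuration <- function(x) length(x@samples) / x@rate

setMethod("show", "BreathRecording", function(object) {
  cat(sprintf("BreathRecording: %s route, %.2f s @ %g Hz\n",
              object@route, recordingDuration(object), object@rate))
})

#' SoundCohort: subjects, anthropometrics, and breathing recordings
#'
#' A cohort is a subject table (id, AHI, severity, age, sex, BMI, neck
#' circumference, Mallampati score) plus, optionally, one nose-route and one
#' mouth-route [BreathRecording-class] per subject.
#'
#' @slot subjects `DataFrame` with columns `subject_id, ahi, severity, age,
#'   sex, bmi, nc, mps`. Severity is always the deterministic image of AHI
#'   under the clinical cut-offs (see [severityFromAhi()]).
#' @slot recordings Named list (by `subject_id`) of lists with elements
#'   `nose` and `mouth`; may be empty when the cohort is anthropometrics-only.
#' @slot spec The [CohortSpec-class] that generated the cohort (or NULL slotwise
#'   via an empty list when externally loaded).
#' @export
setClass("SoundCohort",
  representation(subjects = "DataFrame", recordings = "list", spec = "list"),
  validity = function(object) {
    need <- c("subject_id", "ahi", "severity", "age", "sex", "bmi", "nc", "mps")
    msg <- NULL
    if (!all(need %in% colnames(object@subjects)))
      msg <- c(msg, paste("subject table must contain:", paste(need, collapse = ", ")))
    else {
      if (anyDuplicated(object@subjects$subject_id)) msg <- c(msg, "duplicate subject ids")
      bad <- !object@subjects$severity %in% severityLevels()
      if (any(bad)) msg <- c(msg, "unknown severity labels")
      ok <- stats::complete.cases(as.data.frame(object@subjects[, c("ahi", "severity")]))
      if (any(object@subjects$ahi[ok] < 0)) msg <- c(msg, "negative AHI")
      if (length(object@recordings) &&
          !all(names(object@recordings) %in% object@subjects$subject_id))
        msg <- c(msg, "recordings keyed by unknown subject ids")
    }
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "SoundCohort", function(object) {
  tab <- table(factor(object@subjects$severity, levels = severityLevels()))
  cat(sprintf("SoundCohort: %d subjects (%s)%s\n",
              nrow(object@subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              if (length(object@recordings)) " with audio" else ""))
})

#' @describeIn SoundCohort-class number of subjects
#' @param x a SoundCohort
#' @export
cohortSize <- function(x) nrow(x@subjects)

#' @describeIn SoundCohort-class subject table as a base data.frame
#' @export
subjectTable <- function(x) as.data.frame(x@subjects)

#' @describeIn SoundCohort-class recordings for one subject
#' @param id subject id
#' @export
subjectRecordings <- function(x, id) x@recordings[[id]]

#' FeatureTable: subjects-by-features matrix with explicit missingness
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] with
#' features as rows and subjects as columns. Two assays are kept congruent:
#' `values` (numeric) and `mask` (logical, TRUE = missing). Row metadata
#' records each feature's family (spectral, hos, time, tf, nonlinear,
#' perturbation, anthropometric); column metadata carries the severity label
#' and raw anthropometrics. Normalization metadata, when fitted, lives in
#' `metadata(x)$norm_meta`.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!all(c("values", "mask") %in% names(assays(object))))
      msg <- c(msg, "assays 'values' and 'mask' required")
    else {
      v <- assay(object, "values"); m <- assay(object, "mask")
      if (!is.logical(m)) msg <- c(msg, "mask must be logical")
      else if (any(is.na(v) & !m)) msg <- c(msg, "NA value not flagged in mask")
    }
    if (!"family" %in% colnames(rowData(object)))
      msg <- c(msg, "rowData must record feature family")
    if (!"severity" %in% colnames(colData(object)))
      msg <- c(msg, "colData must record severity")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a FeatureTable
#'
#' @param values numeric matrix, features x subjects
#' @param family character vector of feature families (length nrow)
#' @param severity severity label per subject (length ncol)
#' @param mask logical matrix of the same shape as `values`; defaults to
#'   `is.na(values)`
#' @param colData optional extra per-subject columns (DataFrame/data.frame)
#' @return A [FeatureTable-class].
#' @export
FeatureTable <- function(values, family, severity, mask = NULL, colData = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- is.na(values)
  cd <- DataFrame(severity = severity)
  if (!is.null(colData)) cd <- cbind(cd, DataFrame(colData))
  rownames(cd) <- colnames(values)
  se <- SummarizedExperiment(
    assays = list(values = values, mask = mask),
    rowData = DataFrame(family = family, row.names = rownames(values)),
    colData = cd
  )
  new("FeatureTable", se)
}

#' @describeIn FeatureTable-class the numeric value matrix (features x subjects)
#' @param x a FeatureTable
#' @export
featureValues <- function(x) assay(x, "values")

#' @describeIn FeatureTable-class logical missingness mask (TRUE = missing)
#' @export
missingMask <- function(x) assay(x, "mask")

#' @describeIn FeatureTable-class per-feature family labels
#' @export
featureFamily <- function(x) stats::setNames(as.character(rowData(x)$family), rownames(x))

#' @describeIn FeatureTable-class severity label per subject
#' @export
severityLabels <- function(x) as.character(colData(x)$severity)

#' @describeIn FeatureTable-class names of the anthropometric features
#' @export
anthropometricFeatures <- function(x) rownames(x)[featureFamily(x) == "anthropometric"]

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d features x %d subjects (%d missing cells, %d families)%s\n",
              nrow(object), ncol(object), sum(assay(object, "mask")),
              length(unique(rowData(object)$family)),
              if (!is.null(metadata(object)$norm_meta)) ", normalized" else ""))
})

#' OvoBundle: the six one-vs-one bagged base models
#'
#' @slot tasks list of class pairs, canonical severity-rank order.
#' @slot models list (per task) of bagged ensembles; each records its member
#'   fits, bootstrap row indices, candidate family, and tuned hyperparameters.
#' @slot features list (per task) of the selected feature names used.
#' @slot oob list (per task) of out-of-bag metrics.
#' @slot searchLog data.frame of the hyperparameter-search trace.
#' @export
setClass("OvoBundle",
  representation(tasks = "list", models = "list", features = "list",
                 oob = "list", searchLog = "data.frame"))

setMethod("show", "OvoBundle", function(object) {
  cat(sprintf("OvoBundle: %d pairwise tasks\n", length(object@tasks)))
  for (i in seq_along(object@tasks)) {
    t <- object@tasks[[i]]
    acc <- object@oob[[i]]$balanced_accuracy
    cat(sprintf("  %s vs %s: %s, %d features, OOB bal.acc %.3f\n",
                t[1], t[2], object@models[[i]]$family,
                length(object@features[[i]]),
                if (is.null(acc)) NA_real_ else acc))
  }
})

#' MetaModel: stacked classifier over the 12 base scores
#'
#' @slot scheme class scheme, see [classScheme()].
#' @slot learner fitted meta-learner (family-tagged list).
#' @slot candidateLog data.frame of candidate scores during selection.
#' @slot seed integer seed used for training.
#' @export
setClass("MetaModel",
  representation(scheme = "list", learner = "list",
                 candidateLog = "data.frame", seed = "integer"))

setMethod("show", "MetaModel", function(object) {
  cat(sprintf("MetaModel (%s scheme: %s): %s learner over 12 base scores\n",
              object@scheme$name, paste(object@scheme$classes, collapse = "/"),
              object@learner$family))
})

#' ConformalCalibration: split-conformal threshold state
#'
#' @slot alpha significance level in (0, 1).
#' @slot calibScores nonconformity scores of the calibration rows.
#' @slot qHat the (1 - alpha) augmented empirical quantile (may be `Inf`).
#' @slot nCalib number of calibration rows.
#' @export
setClass("ConformalCalibration",
  representation(alpha = "numeric", calibScores = "numeric",
                 qHat = "numeric", nCalib = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must lie in (0,1)")
    if (any(object@calibScores < 0 | object@calibScores > 1))
      msg <- c(msg, "nonconformity scores must lie in [0,1]")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "ConformalCalibration", function(object) {
  cat(sprintf("ConformalCalibration: alpha=%.3g, n=%d, q_hat=%s\n",
              object@alpha, object@nCalib, format(object@qHat)))
})

#' ConformalSets: per-subject label prediction sets
#'
#' @slot membership logical matrix, subjects x classes (TRUE = label in set).
#' @slot scores numeric matrix of per-label nonconformity scores.
#' @slot qUsed threshold used to build the sets.
#' @export
setClass("ConformalSets",
  representation(membership = "matrix", scores = "matrix", qUsed = "numeric"))

setMethod("show", "ConformalSets", function(object) {
  cat(sprintf("ConformalSets: %d subjects, %d classes, mean set size %.2f (q=%s)\n",
              nrow(object@membership), ncol(object@membership),
              mean(rowSums(object@membership)), format(object@qUsed)))
})

#' @describeIn ConformalSets-class list of label sets, one per subject
#' @param x a ConformalSets
#' @export
setLabels <- function(x) {
  cls <- colnames(x@membership)
  lapply(seq_len(nrow(x@membership)), function(i) cls[x@membership[i, ]])
}

#' @describeIn ConformalSets-class integer set size per subject
#' @export
setSizes <- function(x) rowSums(x@membership)
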
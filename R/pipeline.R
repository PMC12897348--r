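#' Fit the full severity pipeline on training rows
#'
#' In order: stratified k-NN imputation (donors restricted to the training
#' rows), adaptive normalization (fitted on training rows, applied
#' everywhere), a stratified calibration holdout from the training rows,
#' per-task three-stage feature selection (optional), the six bagged
#' one-vs-one base models on the fit rows, the stacked meta-model on their
#' out-of-bag scores, and conformal calibration on the held-out
#' calibration rows via the deployed meta-model's probabilities.
#'
#' @param table a [FeatureTable-class]
#' @param scheme `"three"` or `"four"`
#' @param trainIdx training column indices
#' @param holdout calibration fraction of the training rows
#' @param alpha conformal significance level
#' @param impute,normalize,select stage switches
#' @param candidates,metaCandidates,B,budget,targetK learner settings
#' @param seed integer seed
#' @param ... extra arguments to [selectTaskFeatures()]
#' @return List: `table` (prepared), `scheme`, `bundle`, `meta`,
#'   `calibration`, `fitIdx`, `calibIdx`, `trainIdx`.
#' @export
fitOsaPipeline <- function(table, scheme = "four", trainIdx = seq_len(ncol(table)),
                           holdout = 0.2, alpha = 0.05,
                           impute = TRUE, normalize = TRUE, select = TRUE,
                           candidates = c("logistic", "svmRbf", "randomForest"),
                           metaCandidates = c("mlp", "multinomial"),
                           B = 25L, budget = 8L, targetK = 30L, seed = 1L, ...) {
  sch <- if (is.character(scheme)) classScheme(scheme) else scheme
  if (impute && any(missingMask(table)))
    table <- suppressWarnings(stratifiedKnnImpute(table, donorIdx = trainIdx))
  if (normalize) table <- adaptiveNormalize(table, trainIdx = trainIdx)
  sev <- severityLabels(table)
  sp <- calibrationSplit(applyScheme(sev[trainIdx], sch), holdout = holdout,
                         seed = deriveSeed(seed, 11L))
  fitIdx <- trainIdx[sp$fit]; calibIdx <- trainIdx[sp$calib]
  bundle <- trainOvoBundle(table, subjects = fitIdx, select = select,
                           candidates = candidates, B = B, budget = budget,
                           targetK = targetK, seed = deriveSeed(seed, 21L), ...)
  metaX <- buildMetaFeatures(bundle, table, fitIdx, useOob = TRUE)
  meta <- trainMeta(metaX, sev[fitIdx], scheme = sch,
                    candidates = metaCandidates, seed = deriveSeed(seed, 31L))
  calibProbs <- predictProba(meta, buildMetaFeatures(bundle, table, calibIdx))
  truthCols <- match(applyScheme(sev[calibIdx], sch), colnames(calibProbs))
  calScores <- nonconformity(calibProbs[cbind(seq_along(calibIdx), truthCols)])
  calibration <- fitThreshold(calScores, alpha)
  list(table = table, scheme = sch, bundle = bundle, meta = meta,
       calibration = calibration, fitIdx = fitIdx, calibIdx = calibIdx,
       trainIdx = trainIdx)
}

#' Predict with a fitted pipeline
#'
#' @param fit result of [fitOsaPipeline()]
#' @param table a [FeatureTable-class] prepared like `fit$table` (pass
#'   `fit$table` to score columns of the training table)
#' @param subjects column indices to score
#' @return List: `probs` (scheme-class probabilities), `class` (point
#'   predictions), `sets` (conformal [ConformalSets-class]), `metaX`.
#' @export
predictPipeline <- function(fit, table = fit$table, subjects) {
  metaX <- buildMetaFeatures(fit$bundle, table, subjects)
  probs <- predictProba(fit$meta, metaX)
  list(probs = probs,
       class = colnames(probs)[max.col(probs, ties.method = "first")],
       sets = predictSets(probs, fit$calibration),
       metaX = metaX)
}

#' Default run configuration
#'
#' @param ... overrides of the default fields
#' @return Named list with cohort, pipeline, and output settings.
#' @export
runConfig <- function(...) {
  cfg <- list(
    classSizes = c(non = 74, mild = 35, moderate = 50, severe = 40),
    effectSize = 1, missingRate = 0, rate = 16000, cycles = 5,
    scheme = "four", testFraction = 0.15, holdout = 0.2, alpha = 0.05,
    nTrials = 25L, seed = 1L,
    candidates = c("logistic", "svmRbf", "randomForest"),
    metaCandidates = c("mlp", "multinomial"),
    B = 25L, budget = 8L, targetK = 30L, select = TRUE,
    outDir = tempfile("osascreen_run_")
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$scheme %in% c("three", "four"))
  cfg
}

#' Load a run configuration from YAML
#' @param path YAML file with configuration overrides
#' @return Configuration list (defaults filled in).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$classSizes)) y$classSizes <- unlist(y$classSizes)
  do.call(runConfig, y)
}

#' Simulate a cohort to disk
#'
#' Generates the configured synthetic cohort and writes per-subject WAV
#' recordings, a manifest CSV (`subject_id, ahi, severity, age, sex, bmi,
#' nc, mps, nose_wav, mouth_wav`), and the cohort specification as YAML.
#'
#' @param config from [runConfig()]
#' @return The output directory, invisibly.
#' @export
runSimulate <- function(config = runConfig()) {
  spec <- cohortSpec(classSizes = config$classSizes,
                     acousticEffectSize = config$effectSize,
                     missingRate = config$missingRate,
                     rate = config$rate, cycles = config$cycles,
                     seed = config$seed)
  cohort <- generateCohort(spec)
  dir.create(file.path(config$outDir, "audio"), recursive = TRUE, showWarnings = FALSE)
  tab <- subjectTable(cohort)
  tab$nose_wav <- file.path("audio", paste0(tab$subject_id, "_nose.wav"))
  tab$mouth_wav <- file.path("audio", paste0(tab$subject_id, "_mouth.wav"))
  for (i in seq_len(nrow(tab))) {
    recs <- subjectRecordings(cohort, tab$subject_id[i])
    writeWav(recs$nose, file.path(config$outDir, tab$nose_wav[i]))
    writeWav(recs$mouth, file.path(config$outDir, tab$mouth_wav[i]))
  }
  utils::write.csv(tab, file.path(config$outDir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(list(classSizes = as.list(spec$classSizes),
                        acousticEffectSize = spec$acousticEffectSize,
                        missingRate = spec$missingRate, rate = spec$rate,
                        cycles = spec$cycles, seed = spec$seed),
                   file.path(config$outDir, "spec.yaml"))
  invisible(config$outDir)
}

#' Load a simulated cohort from disk
#' @param dir directory written by [runSimulate()]
#' @return A [SoundCohort-class].
#' @export
readCohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(seq_len(nrow(tab)), function(i) list(
    nose = readWav(file.path(dir, tab$nose_wav[i]), "nose"),
    mouth = readWav(file.path(dir, tab$mouth_wav[i]), "mouth")))
  names(recs) <- tab$subject_id
  new("SoundCohort",
      subjects = DataFrame(tab[, c("subject_id", "ahi", "severity", "age",
                                   "sex", "bmi", "nc", "mps")]),
      recordings = recs, spec = list())
}

#' End-to-end run: cohort to evaluation report
#'
#' Executes split, preprocessing, feature extraction, preparation and
#' selection, base and meta training, conformal calibration, and test
#' evaluation, writing a JSON report plus prediction-set CSVs.
#'
#' @param config from [runConfig()]
#' @param cohort optional pre-built [SoundCohort-class] (else generated)
#' @param table optional pre-extracted [FeatureTable-class] (skips audio)
#' @return List: `fit`, `prediction`, `evaluation`, `report`, `outDir`.
#' @export
runFull <- function(config = runConfig(), cohort = NULL, table = NULL) {
  t0 <- Sys.time()
  if (is.null(table)) {
    if (is.null(cohort)) {
      spec <- cohortSpec(classSizes = config$classSizes,
                         acousticEffectSize = config$effectSize,
                         missingRate = config$missingRate,
                         rate = config$rate, cycles = config$cycles,
                         seed = config$seed)
      cohort <- generateCohort(spec)
    }
    table <- extractFeatures(cohort)
    if (config$missingRate > 0)
      table <- injectMissingness(table, config$missingRate,
                                 seed = deriveSeed(config$seed, 5L))
  }
  sp <- stratifiedSplit(subjectTableFromFeatures(table), config$testFraction,
                        seed = deriveSeed(config$seed, 1L))
  fit <- fitOsaPipeline(table, scheme = config$scheme, trainIdx = sp$train,
                        holdout = config$holdout, alpha = config$alpha,
                        select = config$select, candidates = config$candidates,
                        metaCandidates = config$metaCandidates,
                        B = config$B, budget = config$budget,
                        targetK = config$targetK, seed = config$seed)
  pred <- predictPipeline(fit, fit$table, sp$test)
  truth <- applyScheme(severityLabels(table)[sp$test], fit$scheme)
  ev <- confusionAndMetrics(pred$class, truth, fit$scheme$classes, scores = pred$probs)
  report <- list(
    scheme = fit$scheme$name,
    n_train = length(sp$train), n_test = length(sp$test),
    accuracy = ev$accuracy, macro_sensitivity = ev$macro_sensitivity,
    macro_specificity = ev$macro_specificity,
    per_class = ev$per_class, auc = as.list(ev$auc),
    conformal = list(alpha = config$alpha,
                     q_hat = fit$calibration@qHat,
                     coverage = coverage(pred$sets, truth),
                     avg_set_size = avgSetSize(pred$sets)),
    oob = fit$bundle@oob,
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    seed = config$seed)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mem <- pred$sets@membership
  long <- data.frame(
    subject_id = rep(rownames(pred$probs), ncol(mem)),
    label = rep(colnames(mem), each = nrow(mem)),
    included = as.integer(mem),
    score = as.numeric(pred$sets@scores))
  utils::write.csv(long, file.path(config$outDir, "prediction_sets.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(subject_id = rownames(pred$probs), as.data.frame(mem + 0)),
                   file.path(config$outDir, "set_map.csv"), row.names = FALSE)
  yaml::write_yaml(config[setdiff(names(config), "outDir")],
                   file.path(config$outDir, "config.yaml"))
  list(fit = fit, prediction = pred, evaluation = ev, report = report,
       outDir = config$outDir)
}

#' Compare the meta-model to each base model
#'
#' Builds per-sample correctness vectors on the given rows for the stacked
#' meta-model and for each base model (each base model votes through its
#' own pairwise probabilities projected to the scheme by majority over
#' tasks it participates in; rows outside both its classes count as
#' incorrect), then applies the paired comparison statistics with
#' Bonferroni correction over the six comparisons.
#'
#' @param fit a fitted pipeline from [fitOsaPipeline()]
#' @param table the feature table
#' @param subjects evaluation column indices
#' @return data.frame, one row per base model, mirroring the comparison
#'   statistics, with `bonferroni_alpha` metadata attribute.
#' @export
runCompare <- function(fit, table = fit$table, subjects) {
  sev <- applyScheme(severityLabels(table)[subjects], fit$scheme)
  pred <- predictPipeline(fit, table, subjects)
  metaCorrect <- as.integer(pred$class == sev)
  m <- length(fit$bundle@tasks)
  out <- list()
  for (ti in seq_len(m)) {
    task <- fit$bundle@tasks[[ti]]
    model <- fit$bundle@models[[ti]]
    X <- designMatrix(table, model$featureNames, subjects)
    p2 <- .bagProb(model$members, .baseFamilies()[[model$family]], X)
    basePred <- ifelse(p2 > 0.5, task[2], task[1])
    baseCorrect <- as.integer(applyScheme(basePred, fit$scheme) == sev)
    cc <- compareClassifiers(metaCorrect, baseCorrect, m = m)
    out[[ti]] <- data.frame(
      comparison = sprintf("meta_vs_%s", paste(task, collapse = "_vs_")),
      p_ttest = cc$p_ttest, p_wilcoxon = cc$p_wilcoxon, p_mcnemar = cc$p_mcnemar,
      mean_delta_accuracy = cc$mean_delta_accuracy, cohens_d = cc$cohens_d,
      cliffs_delta = cc$cliffs_delta, p_bonferroni = cc$p_bonferroni)
  }
  res <- do.call(rbind, out)
  attr(res, "bonferroni_alpha") <- 0.05 / m
  res
}
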
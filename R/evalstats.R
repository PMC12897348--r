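#' Confusion matrix and macro metrics
#'
#' Accuracy, per-class sensitivity TP/(TP+FN) and specificity TN/(TN+FP),
#' their unweighted macro averages, and (when score columns are supplied)
#' one-vs-rest AUC per class. Rates are reported in percent. Classes
#' absent from the truths are excluded from the macro averages with a
#' warning.
#'
#' @param preds predicted class labels
#' @param truths true class labels
#' @param classes ordered class labels
#' @param scores optional probability matrix (columns named by class) for AUC
#' @return List with `confusion` (truth rows x prediction columns),
#'   `accuracy`, `macro_sensitivity`, `macro_specificity`, `per_class`,
#'   `auc` (or NULL).
#' @export
confusionAndMetrics <- function(preds, truths, classes = sort(unique(truths)),
                                scores = NULL) {
  stopifnot(length(preds) == length(truths))
  cm <- table(factor(truths, levels = classes), factor(preds, levels = classes))
  total <- sum(cm)
  perClass <- lapply(classes, function(cl) {
    i <- match(cl, classes)
    tp <- cm[i, i]; fn <- sum(cm[i, -i]); fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    list(class = cl,
         sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
  })
  sens <- vapply(perClass, `[[`, numeric(1), "sensitivity")
  spec <- vapply(perClass, `[[`, numeric(1), "specificity")
  if (any(is.na(sens)))
    warning("classes absent from truths excluded from macro averages")
  auc <- NULL
  if (!is.null(scores)) {
    auc <- vapply(classes, function(cl) {
      truth01 <- as.integer(truths == cl)
      if (length(unique(truth01)) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(truth01, scores[, cl], quiet = TRUE,
                                     direction = "<")))
    }, numeric(1))
  }
  list(confusion = cm,
       accuracy = 100 * sum(diag(cm)) / total,
       macro_sensitivity = mean(sens, na.rm = TRUE),
       macro_specificity = mean(spec, na.rm = TRUE),
       per_class = perClass, auc = auc)
}

#' Mean and sample standard deviation over folds
#'
#' @param values numeric vector of per-fold metric values (>= 2)
#' @return List `mean`, `sd` (n - 1 denominator).
#' @export
meanSdOverFolds <- function(values) {
  if (length(values) < 2L) stop("need at least 2 fold values")
  list(mean = mean(values), sd = stats::sd(values))
}

#' Non-parametric bootstrap percentile confidence interval
#'
#' @param x metric samples
#' @param B bootstrap resamples
#' @param level confidence level
#' @param seed integer seed
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrapCi <- function(x, B = 1000L, level = 0.95, seed = 1L) {
  stopifnot(length(x) >= 2L)
  means <- withSeed(seed, vapply(seq_len(B), function(b)
    mean(sample(x, length(x), replace = TRUE)), numeric(1)))
  unname(stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Repeated independent evaluation trials
#'
#' Reruns a train/evaluate closure over independent seeds and aggregates
#' each returned metric as mean, SD, and bootstrap CI.
#'
#' @param runFun function(seed) returning a named numeric vector of metrics
#' @param nTrials number of trials (default 25)
#' @param seeds optional explicit seed vector (length `nTrials`)
#' @param baseSeed used to derive per-trial seeds when `seeds` is NULL
#' @return List with `trials` (matrix, trial x metric) and `summary`
#'   (data.frame of mean, sd, ci_lower, ci_upper).
#' @export
repeatedTrials <- function(runFun, nTrials = 25L, seeds = NULL, baseSeed = 1L) {
  stopifnot(nTrials >= 1L)
  if (is.null(seeds)) seeds <- vapply(seq_len(nTrials), function(i)
    deriveSeed(baseSeed, i), integer(1))
  stopifnot(length(seeds) == nTrials)
  rows <- lapply(seeds, runFun)
  trials <- do.call(rbind, rows)
  summary <- data.frame(
    metric = colnames(trials),
    mean = colMeans(trials),
    sd = if (nTrials > 1L) apply(trials, 2, stats::sd) else NA_real_,
    row.names = NULL)
  if (nTrials > 1L) {
    ci <- t(apply(trials, 2, bootstrapCi, seed = baseSeed))
    summary$ci_lower <- ci[, 1]; summary$ci_upper <- ci[, 2]
  }
  list(trials = trials, summary = summary, seeds = seeds)
}

#' Learning-curve analysis
#'
#' Trains on progressively larger stratified fractions of the training
#' rows while evaluating on a fixed held-out test set.
#'
#' @param table a [FeatureTable-class]
#' @param trainIdx,testIdx fixed train/test column indices
#' @param fractions training-set fractions in (0, 1]
#' @param scheme `"three"` or `"four"`
#' @param seeds one run per seed at each fraction
#' @param ... pipeline settings passed to [fitOsaPipeline()]
#' @return data.frame with one row per (fraction, seed): accuracy,
#'   macro sensitivity/specificity (percent).
#' @export
learningCurve <- function(table, trainIdx, testIdx,
                          fractions = c(0.2, 0.4, 0.6, 0.8, 1.0),
                          scheme = "four", seeds = 1:3, ...) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  sev <- severityLabels(table)
  out <- list()
  for (fr in fractions) {
    for (sd_ in seeds) {
      sub <- unlist(lapply(unique(sev[trainIdx]), function(cl) {
        ix <- trainIdx[sev[trainIdx] == cl]
        nKeep <- max(1L, round(fr * length(ix)))
        withSeed(deriveSeed(sd_, match(cl, severityLevels()), round(100 * fr)),
                 sample(ix, nKeep))
      }))
      counts <- table(sev[sub])
      if (length(counts) < length(unique(sev[trainIdx])) || any(counts < 5L)) {
        warning(sprintf("fraction %.2f leaves a class too small; skipped", fr))
        next
      }
      res <- fitOsaPipeline(table, scheme = scheme, trainIdx = sub,
                            seed = deriveSeed(sd_, 999L), ...)
      pred <- predictPipeline(res, table, testIdx)
      ev <- confusionAndMetrics(pred$class, applyScheme(sev[testIdx], res$scheme),
                                res$scheme$classes)
      out[[length(out) + 1L]] <- data.frame(
        fraction = fr, seed = sd_, accuracy = ev$accuracy,
        sensitivity = ev$macro_sensitivity, specificity = ev$macro_specificity)
    }
  }
  do.call(rbind, out)
}

#' Paired classifier comparison statistics
#'
#' Given aligned per-sample correctness vectors of two classifiers:
#' paired t-test and Wilcoxon signed-rank test (zero differences dropped)
#' on the per-sample outcomes, exact-binomial McNemar test on the
#' discordant pairs, mean accuracy difference, Cohen's d on the paired
#' differences, Cliff's delta over all value pairs, and the
#' Bonferroni-adjusted t-test p-value for `m` comparisons.
#'
#' @param correctA,correctB binary (0/1) correctness vectors, aligned
#' @param m number of comparisons in the family (Bonferroni)
#' @return List of statistics (see fields); when all differences are zero
#'   the t/Wilcoxon p-values are 1 by convention and `degenerate = TRUE`.
#' @export
compareClassifiers <- function(correctA, correctB, m = 1L) {
  stopifnot(length(correctA) == length(correctB), length(correctA) >= 5L)
  a <- as.numeric(correctA); b <- as.numeric(correctB)
  d <- a - b
  degenerate <- all(d == 0) || stats::sd(d) == 0
  if (degenerate) {
    pT <- 1; pW <- 1; cohD <- 0
  } else {
    pT <- stats::t.test(a, b, paired = TRUE)$p.value
    nz <- d[d != 0]
    pW <- suppressWarnings(stats::wilcox.test(nz)$p.value)
    cohD <- mean(d) / stats::sd(d)
  }
  n01 <- sum(a == 1 & b == 0)   # A correct where B wrong
  n10 <- sum(a == 0 & b == 1)
  pMc <- if (n01 + n10 == 0) 1 else stats::binom.test(n01, n01 + n10)$p.value
  cliff <- (sum(outer(a, b, ">")) - sum(outer(a, b, "<"))) / (length(a) * length(b))
  list(p_ttest = pT, p_wilcoxon = pW, p_mcnemar = pMc,
       mean_delta_accuracy = mean(d), cohens_d = cohD, cliffs_delta = cliff,
       p_bonferroni = min(1, pT * m),
       bonferroni_alpha = 0.05 / m,
       discordant = c(a_only = n01, b_only = n10),
       degenerate = degenerate)
}
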
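#' Stage 1: univariate Welch t-test filter
#'
#' Keeps features whose two-sided Welch two-sample t-test p-value between
#' the two task classes is below `alpha`. Features with zero variance in
#' both classes get p = 1 by convention and are removed.
#'
#' @param X numeric matrix, subjects x features
#' @param y binary task labels (length nrow(X))
#' @param alpha significance threshold
#' @return Character vector of kept feature names.
#' @export
ttestFilter <- function(X, y, alpha = 0.05) {
  lev <- unique(y)
  stopifnot(length(lev) == 2L)
  a <- X[y == lev[1], , drop = FALSE]; b <- X[y == lev[2], , drop = FALSE]
  p <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(a[, j]) == 0 && stats::sd(b[, j]) == 0) return(1)
    tryCatch(stats::t.test(a[, j], b[, j])$p.value, error = function(e) 1)
  }, numeric(1))
  colnames(X)[p < alpha]
}

#' Stage 2: SHAP-based feature ranking
#'
#' Fits a gradient-boosted tree ensemble on the kept features and ranks
#' them by mean absolute SHAP attribution over the training rows
#' (TreeSHAP, descending). Deterministic under a fixed seed.
#'
#' @param X numeric matrix, subjects x features
#' @param y binary task labels
#' @param features candidate feature names (stage-1 output)
#' @param nrounds,maxDepth,eta boosting parameters
#' @param seed integer seed
#' @return Named numeric vector of mean |SHAP| scores, sorted descending;
#'   names are the ranked features.
#' @export
shapRank <- function(X, y, features = colnames(X), nrounds = 60L,
                     maxDepth = 3L, eta = 0.3, seed = 1L) {
  Xs <- X[, features, drop = FALSE]
  lab <- as.numeric(y == sort(unique(y))[2])
  dm <- xgboost::xgb.DMatrix(Xs, label = lab, nthread = 1L)
  bst <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                          max_depth = maxDepth, eta = eta,
                                          nthread = 1L, seed = seed),
                            data = dm, nrounds = nrounds)
  contrib <- predict(bst, dm, predcontrib = TRUE)
  s <- colMeans(abs(contrib[, features, drop = FALSE]))
  sort(s, decreasing = TRUE)
}

#' Boosting with random undersampling (RUSBoost-style)
#'
#' AdaBoost.M1 over shallow CART trees where each weak learner is trained
#' on a class-balanced subset obtained by randomly undersampling the
#' majority class (sampled according to the current boosting weights).
#'
#' @param X numeric matrix, subjects x features
#' @param y binary labels
#' @param nIter boosting iterations
#' @param maxDepth weak-learner tree depth
#' @param seed integer seed
#' @return A fitted model (list) for [rusboostPredict()] /
#'   [rusboostImportance()].
#' @export
rusboostFit <- function(X, y, nIter = 25L, maxDepth = 2L, seed = 1L) {
  lev <- sort(unique(y))
  stopifnot(length(lev) == 2L)
  yy <- ifelse(y == lev[2], 1, -1)
  n <- nrow(X)
  df <- data.frame(X, check.names = FALSE)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  withSeed(seed, {
    for (it in seq_len(nIter)) {
      idx1 <- which(yy > 0); idx0 <- which(yy < 0)
      nMin <- min(length(idx1), length(idx0))
      take <- function(ix) if (length(ix) > nMin)
        sample(ix, nMin, prob = w[ix] / sum(w[ix])) else ix
      sub <- c(take(idx1), take(idx0))
      fit <- rpart::rpart(factor(yy[sub]) ~ ., data = df[sub, , drop = FALSE],
                          weights = w[sub] / mean(w[sub]),
                          method = "class",
                          control = rpart::rpart.control(maxdepth = maxDepth,
                                                         cp = 0, minsplit = 4,
                                                         xval = 0))
      h <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
      err <- sum(w[h != yy])
      if (err >= 0.5 || err <= 1e-10) {
        if (err <= 1e-10) { trees[[length(trees) + 1L]] <- fit; alphas <- c(alphas, 4) }
        if (err <= 1e-10) break else next
      }
      a <- 0.5 * log((1 - err) / err)
      trees[[length(trees) + 1L]] <- fit
      alphas <- c(alphas, a)
      w <- w * exp(-a * yy * h)
      w <- w / sum(w)
    }
  })
  if (!length(trees)) {  # degenerate: single majority-vote stump
    trees <- list(rpart::rpart(factor(yy) ~ ., data = df, method = "class",
                               control = rpart::rpart.control(maxdepth = 1, cp = 0, xval = 0)))
    alphas <- 1
  }
  list(trees = trees, alphas = alphas, levels = lev, features = colnames(X))
}

#' Predict with a RUSBoost-style model
#' @param model fit from [rusboostFit()]
#' @param X subjects x features matrix
#' @param type `"class"` or `"prob"` (probability of the second level)
#' @return Labels or probabilities.
#' @export
rusboostPredict <- function(model, X, type = c("class", "prob")) {
  type <- match.arg(type)
  df <- data.frame(X[, model$features, drop = FALSE], check.names = FALSE)
  margin <- rowSums(vapply(seq_along(model$trees), function(i) {
    h <- ifelse(predict(model$trees[[i]], df, type = "class") == "1", 1, -1)
    model$alphas[i] * h
  }, numeric(nrow(df))))
  if (type == "prob") return(1 / (1 + exp(-2 * margin)))
  ifelse(margin > 0, model$levels[2], model$levels[1])
}

#' Feature importance of a RUSBoost-style model
#' @param model fit from [rusboostFit()]
#' @return Named importance vector over the model's features (zeros for
#'   unused features).
#' @export
rusboostImportance <- function(model) {
  imp <- stats::setNames(numeric(length(model$features)), model$features)
  for (i in seq_along(model$trees)) {
    vi <- model$trees[[i]]$variable.importance
    if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + model$alphas[i] * vi
  }
  imp
}

# Stratified fold ids for internal CV.
.cvFolds <- function(y, k, seed) {
  f <- integer(length(y))
  withSeed(seed, for (lev in unique(y)) {
    ix <- sample(which(y == lev))
    f[ix] <- rep_len(seq_len(k), length(ix))
  })
  f
}

#' Stage 3: recursive feature elimination with RUSBoost scoring
#'
#' Starting from the SHAP-ranked list, iteratively refits a RUSBoost-style
#' ensemble, drops the weakest `dropFraction` of remaining features by
#' ensemble importance (at least one), and scores each visited subset by
#' stratified `cvFolds`-fold cross-validated balanced accuracy, down to
#' `targetK` features. The five anthropometric features are appended after
#' selection and are never eliminated.
#'
#' @param X numeric matrix, subjects x features (acoustic features)
#' @param y binary task labels
#' @param ranked ranked feature names (stage-2 output, strongest first)
#' @param targetK number of acoustic features to retain (default 30)
#' @param anthro names of the anthropometric features to append
#' @param cvFolds folds for subset scoring
#' @param dropFraction fraction of remaining features dropped per
#'   elimination step
#' @param nIter,maxDepth RUSBoost parameters
#' @param seed integer seed
#' @return A `SelectionReport` list: `stage1_kept` (= input ranking's
#'   universe), `stage2_ranking`, `final_selected` (acoustic, length
#'   `targetK`), `design_features` (with anthropometrics appended),
#'   `cv_path` (size vs score), `thresholds`.
#' @export
rfeSelect <- function(X, y, ranked, targetK = 30L,
                      anthro = c("age", "sex", "bmi", "nc", "mps"),
                      cvFolds = 3L, dropFraction = 0.1,
                      nIter = 25L, maxDepth = 2L, seed = 1L) {
  if (length(ranked) < targetK) {
    warning("fewer ranked features than targetK; keeping all")
    final <- ranked
    path <- data.frame(size = length(ranked), score = NA_real_)
  } else {
    current <- ranked
    path <- list()
    folds <- .cvFolds(y, cvFolds, seed)
    scoreSubset <- function(feats) {
      acc <- vapply(seq_len(cvFolds), function(f) {
        tr <- folds != f
        m <- rusboostFit(X[tr, feats, drop = FALSE], y[tr],
                         nIter = nIter, maxDepth = maxDepth,
                         seed = deriveSeed(seed, f))
        balancedAccuracy(rusboostPredict(m, X[!tr, feats, drop = FALSE]), y[!tr])
      }, numeric(1))
      mean(acc)
    }
    step <- 0L
    repeat {
      step <- step + 1L
      path[[step]] <- data.frame(size = length(current), score = scoreSubset(current))
      if (length(current) <= targetK) break
      m <- rusboostFit(X[, current, drop = FALSE], y,
                       nIter = nIter, maxDepth = maxDepth,
                       seed = deriveSeed(seed, 1000L + step))
      imp <- rusboostImportance(m)
      # rank-stable tie-break: among equal importance, drop the lowest SHAP rank
      ord <- order(imp[current], -match(current, ranked), decreasing = FALSE)
      nDrop <- min(max(1L, ceiling(dropFraction * length(current))),
                   length(current) - targetK)
      current <- setdiff(current, current[ord[seq_len(nDrop)]])
    }
    final <- current
    path <- do.call(rbind, path)
  }
  list(stage1_kept = ranked, stage2_ranking = ranked,
       final_selected = final,
       design_features = c(final, anthro),
       cv_path = path,
       thresholds = list(targetK = targetK, cvFolds = cvFolds,
                         dropFraction = dropFraction))
}

#' Full three-stage per-task feature selection
#'
#' Runs the t-test filter, SHAP ranking, and RUSBoost RFE on the acoustic
#' features of one one-vs-one task, then appends the anthropometric
#' features, giving the task's design feature set (default 30 + 5 = 35).
#'
#' @param table a normalized [FeatureTable-class]
#' @param task length-2 character vector of severity classes
#' @param subjects training column indices to use (task rows are selected
#'   within these)
#' @param alpha stage-1 threshold
#' @param targetK acoustic features to retain
#' @param seed integer seed
#' @param ... passed to [rfeSelect()]
#' @return A `SelectionReport` (see [rfeSelect()]), with `stage1_kept` the
#'   t-test survivors and `stage2_ranking` the SHAP order.
#' @export
selectTaskFeatures <- function(table, task, subjects = seq_len(ncol(table)),
                               alpha = 0.05, targetK = 30L, seed = 1L, ...) {
  sev <- severityLabels(table)[subjects]
  rows <- subjects[sev %in% task]
  y <- severityLabels(table)[rows]
  acoustic <- rownames(table)[featureFamily(table) != "anthropometric"]
  X <- designMatrix(table, acoustic, rows)
  kept <- ttestFilter(X, y, alpha = alpha)
  if (!length(kept)) {
    warning("no features passed the t-test filter; falling back to all acoustic features")
    kept <- acoustic
  }
  ranking <- shapRank(X, y, kept, seed = seed)
  rep <- rfeSelect(X, y, names(ranking), targetK = targetK, seed = seed,
                   anthro = anthropometricFeatures(table), ...)
  rep$stage1_kept <- kept
  rep$stage2_ranking <- ranking
  rep$task <- task
  rep$thresholds$alpha <- alpha
  rep
}
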
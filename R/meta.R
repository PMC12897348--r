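#' Build the 12-column meta-feature matrix
#'
#' Stacks the six base models' pairwise probability scores. For rows the
#' bundle was trained on, out-of-bag scores are used (stacking leakage
#' control); for unseen rows, full-bag scores. Rows lacking OOB coverage
#' for some member fall back to the full-bag score (flagged).
#'
#' @param bundle a trained [OvoBundle-class]
#' @param table the [FeatureTable-class]
#' @param subjects column indices to build rows for
#' @param useOob treat `subjects` as training rows and use OOB scores
#' @return Numeric matrix, subjects x 12, with attribute `oobFallback`
#'   (logical per row) when `useOob = TRUE`.
#' @export
buildMetaFeatures <- function(bundle, table, subjects = seq_len(ncol(table)),
                              useOob = FALSE) {
  full <- predictPairScores(bundle, table, subjects)
  if (!useOob) return(full)
  fams <- .baseFamilies()
  sev <- severityLabels(table)
  fallback <- rep(FALSE, length(subjects))
  out <- full
  for (ti in seq_along(bundle@tasks)) {
    m <- bundle@models[[ti]]
    task <- bundle@tasks[[ti]]
    inTask <- which(sev[subjects] %in% task)
    if (!length(inTask)) next
    # training rows of this task, in the order the model saw them
    trainRows <- which(sev[subjects] %in% task)
    oobProb <- m$oob$prob
    cols <- paste0(paste(task, collapse = "_vs_"), ".", m$classes)
    if (length(oobProb) == length(trainRows)) {
      ok <- !is.na(oobProb)
      out[trainRows[ok], cols[2]] <- oobProb[ok]
      out[trainRows[ok], cols[1]] <- 1 - oobProb[ok]
      fallback[trainRows[!ok]] <- TRUE
    }
  }
  attr(out, "oobFallback") <- fallback
  out
}

# meta-learner candidate families: fit(X, y) -> model, prob(model, X).
.metaFamilies <- function(scheme, seed) {
  hidden <- if (scheme$name == "three") c(16L, 16L) else c(16L, 16L, 8L)
  lr <- if (scheme$name == "three") 7.06e-2 else 5.14e-3
  list(
    mlp = list(
      fit = function(X, y) mlpFit(X, y, hidden = hidden, lr = lr, seed = seed),
      prob = function(m, X) mlpPredict(m, X)),
    multinomial = list(
      fit = function(X, y) {
        df <- data.frame(X, check.names = FALSE)
        withSeed(seed, nnet::multinom(y ~ ., data = cbind(y = factor(y), df),
                                      trace = FALSE, maxit = 200))
      },
      prob = function(m, X) {
        p <- predict(m, data.frame(X, check.names = FALSE), type = "probs")
        if (is.null(dim(p))) p <- cbind(1 - p, p)
        lev <- m$lev
        if (ncol(p) != length(lev)) p <- matrix(p, ncol = length(lev))
        colnames(p) <- lev
        p
      }),
    randomForest = list(
      fit = function(X, y) ranger::ranger(x = data.frame(X, check.names = FALSE),
                                          y = factor(y), probability = TRUE,
                                          num.trees = 200L, num.threads = 1L,
                                          seed = seed),
      prob = function(m, X) predict(m, data.frame(X, check.names = FALSE),
                                    num.threads = 1L)$predictions),
    svmRadial = list(
      fit = function(X, y) e1071::svm(X, factor(y), kernel = "radial",
                                      probability = TRUE),
      prob = function(m, X) {
        p <- attr(predict(m, X, probability = TRUE), "probabilities")
        p[, m$levels, drop = FALSE]
      }),
    svmPoly = list(
      fit = function(X, y) e1071::svm(X, factor(y), kernel = "polynomial",
                                      degree = 3, probability = TRUE),
      prob = function(m, X) {
        p <- attr(predict(m, X, probability = TRUE), "probabilities")
        p[, m$levels, drop = FALSE]
      })
  )
}

#' Train the stacked meta-model
#'
#' Maps raw severity labels through the class scheme, fits each candidate
#' meta-learner on the 12 base scores, selects by balanced accuracy on an
#' internal stratified validation split, and refits the winner on all rows.
#' The default MLP architecture follows the scheme: two hidden layers with
#' learning rate 7.06e-2 for three classes, three hidden layers with
#' learning rate 5.14e-3 for four classes.
#'
#' @param metaX meta-feature matrix from [buildMetaFeatures()]
#' @param severity raw severity labels for the rows
#' @param scheme a [classScheme()]
#' @param candidates candidate names (subset of `mlp`, `multinomial`,
#'   `randomForest`, `svmRadial`, `svmPoly`)
#' @param valFraction validation fraction for candidate selection
#' @param seed integer seed
#' @return A [MetaModel-class].
#' @export
trainMeta <- function(metaX, severity, scheme = classScheme("four"),
                      candidates = c("mlp", "multinomial", "randomForest",
                                     "svmRadial", "svmPoly"),
                      valFraction = 0.2, seed = 1L) {
  y <- applyScheme(severity, scheme)
  if (length(unique(y)) < 2L) stop("degenerate labels: single class")
  fams <- .metaFamilies(scheme, seed)
  if (length(candidates) > 1L) {
    valIdx <- unlist(lapply(unique(y), function(cl) {
      ix <- which(y == cl)
      withSeed(deriveSeed(seed, match(cl, scheme$classes)),
               sample(ix, max(1L, round(valFraction * length(ix)))))
    }))
    trIdx <- setdiff(seq_len(nrow(metaX)), valIdx)
    scores <- vapply(candidates, function(cn) {
      f <- fams[[cn]]
      m <- tryCatch(f$fit(metaX[trIdx, , drop = FALSE], y[trIdx]),
                    error = function(e) NULL)
      if (is.null(m)) return(NA_real_)
      p <- f$prob(m, metaX[valIdx, , drop = FALSE])
      balancedAccuracy(colnames(p)[max.col(p)], y[valIdx])
    }, numeric(1))
    bestName <- candidates[which.max(scores)]
    log <- data.frame(candidate = candidates, val_balanced_accuracy = scores)
  } else {
    bestName <- candidates
    log <- data.frame(candidate = candidates, val_balanced_accuracy = NA_real_)
  }
  f <- fams[[bestName]]
  fit <- f$fit(metaX, y)
  new("MetaModel", scheme = scheme,
      learner = list(family = bestName, fit = fit, prob = f$prob),
      candidateLog = log, seed = as.integer(seed))
}

#' Class probabilities from the stacked meta-model
#'
#' @param meta a [MetaModel-class]
#' @param metaX meta-feature matrix (12 columns)
#' @return Probability matrix, rows x scheme classes (columns in scheme
#'   order, rows summing to 1); `max.col` gives the point prediction.
#' @export
predictProba <- function(meta, metaX) {
  p <- meta@learner$prob(meta@learner$fit, metaX)
  p <- p[, meta@scheme$classes, drop = FALSE]
  p / rowSums(p)
}

#' Point predictions from the stacked meta-model
#' @param meta a [MetaModel-class]
#' @param metaX meta-feature matrix
#' @return Character vector of scheme classes.
#' @export
predictClass <- function(meta, metaX) {
  p <- predictProba(meta, metaX)
  colnames(p)[max.col(p, ties.method = "first")]
}
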
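#' Enumerate one-vs-one binary tasks
#'
#' All unordered class pairs in canonical severity-rank order; four classes
#' give the six pairwise comparisons.
#'
#' @param classes ordered class labels
#' @return List of length-2 character vectors.
#' @export
enumerateTasks <- function(classes = severityLevels()) {
  stopifnot(length(classes) >= 2L)
  out <- list()
  for (i in seq_len(length(classes) - 1L))
    for (j in (i + 1L):length(classes))
      out[[length(out) + 1L]] <- c(classes[i], classes[j])
  out
}

# ---- candidate classifier families -----------------------------------------
# Each family: paramDim, sample (unit-cube -> params), fit(X, y01) -> fit,
# prob(fit, X) -> P(class 2). All emit calibrated probabilities in [0, 1].

.baseFamilies <- function() {
  list(
    logistic = list(
      paramDim = 0L,
      decode = function(u) list(),
      fit = function(X, y01, params, seed) {
        suppressWarnings(stats::glm.fit(cbind(1, X), y01, family = stats::binomial()))
      },
      prob = function(fit, X) {
        eta <- cbind(1, X) %*% ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        as.numeric(1 / (1 + exp(-eta)))
      }),
    svmLinear = list(
      paramDim = 1L,
      decode = function(u) list(cost = 10^(u[1] * 4 - 2)),
      fit = function(X, y01, params, seed) {
        e1071::svm(X, factor(y01), kernel = "linear", cost = params$cost,
                   probability = TRUE, scale = TRUE)
      },
      prob = function(fit, X) {
        attr(predict(fit, X, probability = TRUE), "probabilities")[, "1"]
      }),
    svmRbf = list(
      paramDim = 2L,
      decode = function(u) list(cost = 10^(u[1] * 4 - 2), gamma = 10^(u[2] * 4 - 3)),
      fit = function(X, y01, params, seed) {
        e1071::svm(X, factor(y01), kernel = "radial", cost = params$cost,
                   gamma = params$gamma, probability = TRUE, scale = TRUE)
      },
      prob = function(fit, X) {
        attr(predict(fit, X, probability = TRUE), "probabilities")[, "1"]
      }),
    randomForest = list(
      paramDim = 2L,
      decode = function(u) list(mtryFrac = 0.1 + 0.8 * u[1],
                                minNode = 1L + round(9 * u[2])),
      fit = function(X, y01, params, seed) {
        ranger::ranger(x = data.frame(X, check.names = FALSE), y = factor(y01),
                       num.trees = 100L,
                       mtry = max(1L, round(params$mtryFrac * ncol(X))),
                       min.node.size = params$minNode, probability = TRUE,
                       num.threads = 1L, seed = seed)
      },
      prob = function(fit, X) {
        predict(fit, data.frame(X, check.names = FALSE),
                num.threads = 1L)$predictions[, "1"]
      }),
    mlp = list(
      paramDim = 2L,
      decode = function(u) list(size = 2L + round(10 * u[1]),
                                decay = 10^(u[2] * 4 - 5)),
      fit = function(X, y01, params, seed) {
        withSeed(seed, nnet::nnet(X, y01, size = params$size, decay = params$decay,
                                  entropy = TRUE, maxit = 150, trace = FALSE))
      },
      prob = function(fit, X) as.numeric(predict(fit, X))),
    rusboost = list(
      paramDim = 2L,
      decode = function(u) list(nIter = 10L + round(30 * u[1]),
                                maxDepth = 1L + round(2 * u[2])),
      fit = function(X, y01, params, seed) {
        rusboostFit(X, as.character(y01), nIter = params$nIter,
                    maxDepth = params$maxDepth, seed = seed)
      },
      prob = function(fit, X) rusboostPredict(fit, X, type = "prob"))
  )
}

# ---- bagging ---------------------------------------------------------------

.bagFit <- function(X, y01, family, params, B, seed) {
  n <- nrow(X)
  members <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- withSeed(deriveSeed(seed, b), sample.int(n, n, replace = TRUE))
    # guard: a bootstrap must contain both classes
    tries <- 0L
    while (length(unique(y01[rows])) < 2L && tries < 20L) {
      tries <- tries + 1L
      rows <- withSeed(deriveSeed(seed, b, tries), sample.int(n, n, replace = TRUE))
    }
    fit <- family$fit(X[rows, , drop = FALSE], y01[rows], params,
                      deriveSeed(seed, 10000L + b))
    members[[b]] <- list(fit = fit, rows = rows)
  }
  members
}

.bagProb <- function(members, family, X) {
  p <- vapply(members, function(m) family$prob(m$fit, X), numeric(nrow(X)))
  rowMeans(matrix(p, nrow = nrow(X)))
}

#' Out-of-bag scores for a bagged ensemble
#'
#' For each training row, averages member probabilities over exactly those
#' members whose bootstrap resample excluded the row; rows included in
#' every bootstrap are flagged `NA`.
#'
#' @param members bagged members (each with `fit` and its bootstrap `rows`)
#' @param familyName candidate family name
#' @param X the training design matrix the bag was fitted on
#' @return List with `prob` (OOB probability of the second class, `NA` when
#'   undefined) and `nMembers` (OOB member count per row).
#' @export
oobScores <- function(members, familyName, X) {
  family <- .baseFamilies()[[familyName]]
  n <- nrow(X)
  acc <- numeric(n); cnt <- integer(n)
  for (m in members) {
    outRows <- setdiff(seq_len(n), m$rows)
    if (!length(outRows)) next
    acc[outRows] <- acc[outRows] + family$prob(m$fit, X[outRows, , drop = FALSE])
    cnt[outRows] <- cnt[outRows] + 1L
  }
  prob <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  if (mean(cnt == 0L) > 0.01)
    warning(sprintf("%.1f%% of rows have no OOB member; increase B",
                    100 * mean(cnt == 0L)))
  list(prob = prob, nMembers = cnt)
}

# ---- Gaussian-process expected-improvement search --------------------------

.gpEiPropose <- function(U, scores, nCand = 200L, seed = 1L) {
  d <- ncol(U)
  s <- (scores - mean(scores)) / (stats::sd(scores) + 1e-9)
  K <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-pmax(d2, 0) / (2 * 0.3^2))
  }
  Kxx <- K(U, U) + diag(0.05, nrow(U))
  alpha <- solve(Kxx, s)
  cand <- withSeed(seed, matrix(stats::runif(nCand * d), ncol = d))
  Ksx <- K(cand, U)
  mu <- as.numeric(Ksx %*% alpha)
  var <- pmax(1 - rowSums((Ksx %*% solve(Kxx)) * Ksx), 1e-9)
  sd <- sqrt(var)
  best <- max(s)
  z <- (mu - best) / sd
  ei <- sd * (z * stats::pnorm(z) + stats::dnorm(z))
  cand[which.max(ei), , drop = TRUE]
}

# Bayesian (GP expected-improvement) search over one family's unit-cube
# hyperparameter space, scored by OOB balanced accuracy of a B-member bag.
.searchFamily <- function(X, y01, familyName, B, budget, seed) {
  family <- .baseFamilies()[[familyName]]
  evalPoint <- function(u, k) {
    params <- family$decode(u)
    members <- .bagFit(X, y01, family, params, B, deriveSeed(seed, k))
    oob <- suppressWarnings(oobScores(members, familyName, X))
    ok <- !is.na(oob$prob)
    score <- if (!any(ok)) 0 else
      balancedAccuracy(as.character(as.integer(oob$prob[ok] > 0.5)), as.character(y01[ok]))
    list(score = score, members = members, params = params)
  }
  if (family$paramDim == 0L || budget <= 1L) {
    r <- evalPoint(numeric(0), 1L)
    return(list(score = r$score, members = r$members, params = r$params,
                trace = data.frame(family = familyName, eval = 1L, score = r$score)))
  }
  d <- family$paramDim
  nInit <- min(max(3L, d + 2L), budget)
  U <- withSeed(deriveSeed(seed, 77L), matrix(stats::runif(nInit * d), ncol = d))
  evals <- lapply(seq_len(nInit), function(k) evalPoint(U[k, ], k))
  scores <- vapply(evals, `[[`, numeric(1), "score")
  k <- nInit
  while (k < budget) {
    k <- k + 1L
    u <- .gpEiPropose(U, scores, seed = deriveSeed(seed, 500L + k))
    U <- rbind(U, u)
    evals[[k]] <- evalPoint(u, k)
    scores <- c(scores, evals[[k]]$score)
  }
  best <- which.max(scores)
  list(score = scores[best], members = evals[[best]]$members,
       params = evals[[best]]$params,
       trace = data.frame(family = familyName, eval = seq_len(k), score = scores))
}

#' Train one bagged one-vs-one base model
#'
#' For each candidate classifier family, runs a Gaussian-process
#' expected-improvement hyperparameter search with `budget` evaluations,
#' each scored by out-of-bag balanced accuracy of a `B`-member bagged
#' ensemble, and returns the best family's ensemble.
#'
#' @param X numeric matrix, task subjects x task features
#' @param y task labels (two classes)
#' @param candidates candidate family names (subset of `logistic`,
#'   `svmLinear`, `svmRbf`, `randomForest`, `mlp`, `rusboost`)
#' @param B bag members
#' @param budget search evaluations per family
#' @param seed integer seed
#' @return A bagged-ensemble list: `family`, `params`, `members`, `classes`
#'   (c(negative, positive) in severity order), `featureNames`, `oob`
#'   (per-row OOB probability + metrics), `searchLog`.
#' @export
trainBase <- function(X, y, candidates = c("logistic", "svmLinear", "svmRbf",
                                           "randomForest", "mlp", "rusboost"),
                      B = 50L, budget = 25L, seed = 1L) {
  classes <- intersect(c(severityLevels(), "moderate_severe", sort(unique(y))), unique(y))
  stopifnot(length(classes) == 2L, all(table(y) > 0))
  y01 <- as.integer(y == classes[2])
  results <- list(); traces <- list()
  for (fam in candidates) {
    r <- tryCatch(.searchFamily(X, y01, fam, B, budget, deriveSeed(seed, match(fam, candidates))),
                  error = function(e) {
                    warning("candidate family '", fam, "' failed: ", conditionMessage(e))
                    NULL
                  })
    if (is.null(r)) next
    results[[fam]] <- r
    traces[[fam]] <- r$trace
  }
  if (!length(results)) stop("all candidate families failed")
  bestFam <- names(results)[which.max(vapply(results, `[[`, numeric(1), "score"))]
  best <- results[[bestFam]]
  oob <- suppressWarnings(oobScores(best$members, bestFam, X))
  ok <- !is.na(oob$prob)
  pred <- ifelse(oob$prob > 0.5, classes[2], classes[1])
  metrics <- list(
    balanced_accuracy = balancedAccuracy(pred[ok], y[ok]),
    accuracy = mean(pred[ok] == y[ok]),
    sensitivity = mean(pred[ok & y == classes[2]] == classes[2]),
    specificity = mean(pred[ok & y == classes[1]] == classes[1]))
  list(family = bestFam, params = best$params, members = best$members,
       classes = classes, featureNames = colnames(X),
       oob = c(metrics, list(prob = oob$prob, nMembers = oob$nMembers)),
       searchLog = do.call(rbind, traces))
}

#' Train the full one-vs-one bundle
#'
#' Enumerates the pairwise tasks over the four severity classes, optionally
#' runs per-task three-stage feature selection, and trains one bagged base
#' model per task.
#'
#' @param table a normalized [FeatureTable-class]
#' @param subjects training column indices
#' @param featuresByTask optional list of feature-name vectors per task; if
#'   `NULL` and `select = TRUE`, selection is run per task; if `NULL` and
#'   `select = FALSE`, all features are used for every task
#' @param select run [selectTaskFeatures()] per task
#' @param candidates,B,budget passed to [trainBase()]
#' @param targetK acoustic features kept per task when selecting
#' @param seed integer seed
#' @param ... extra arguments to [selectTaskFeatures()]
#' @return An [OvoBundle-class].
#' @export
trainOvoBundle <- function(table, subjects = seq_len(ncol(table)),
                           featuresByTask = NULL, select = FALSE,
                           candidates = c("logistic", "svmLinear", "svmRbf",
                                          "randomForest", "mlp", "rusboost"),
                           B = 50L, budget = 25L, targetK = 30L, seed = 1L, ...) {
  tasks <- enumerateTasks()
  sev <- severityLabels(table)
  models <- list(); feats <- list(); oob <- list(); logs <- list()
  for (ti in seq_along(tasks)) {
    task <- tasks[[ti]]
    rows <- subjects[sev[subjects] %in% task]
    f <- if (!is.null(featuresByTask)) featuresByTask[[ti]]
         else if (select)
           selectTaskFeatures(table, task, subjects, targetK = targetK,
                              seed = deriveSeed(seed, ti), ...)$design_features
         else rownames(table)
    X <- designMatrix(table, f, rows)
    m <- trainBase(X, sev[rows], candidates = candidates, B = B,
                   budget = budget, seed = deriveSeed(seed, 100L + ti))
    models[[ti]] <- m
    feats[[ti]] <- f
    oob[[ti]] <- m$oob[c("balanced_accuracy", "accuracy", "sensitivity", "specificity")]
    logs[[ti]] <- cbind(task = paste(task, collapse = "_vs_"), m$searchLog)
  }
  new("OvoBundle", tasks = tasks, models = models, features = feats,
      oob = oob, searchLog = do.call(rbind, logs))
}

#' Pairwise probability scores for subjects
#'
#' For each of the six tasks emits both class posterior probabilities
#' (bag-averaged), concatenated in canonical task order: exactly 12 values
#' per subject, each per-task pair summing to 1.
#'
#' @param bundle a trained [OvoBundle-class]
#' @param table a [FeatureTable-class] normalized with the training metadata
#' @param subjects column indices to score
#' @return Numeric matrix, subjects x 12, columns named
#'   `<a>_vs_<b>.<class>`.
#' @export
predictPairScores <- function(bundle, table, subjects = seq_len(ncol(table))) {
  fams <- .baseFamilies()
  out <- NULL
  for (ti in seq_along(bundle@tasks)) {
    m <- bundle@models[[ti]]
    X <- designMatrix(table, m$featureNames, subjects)
    if (any(is.na(X))) stop("missing feature values; impute before scoring")
    p2 <- .bagProb(m$members, fams[[m$family]], X)
    cols <- cbind(1 - p2, p2)
    colnames(cols) <- paste0(paste(bundle@tasks[[ti]], collapse = "_vs_"),
                             ".", m$classes)
    out <- cbind(out, cols)
  }
  rownames(out) <- colnames(table)[subjects]
  out
}
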
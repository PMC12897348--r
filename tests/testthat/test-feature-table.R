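# toy table builder: values is features x subjects
toyTable <- function(values, severity, family = NULL) {
  if (is.null(family)) family <- rep("spectral", nrow(values))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  FeatureTable(values, family = family, severity = severity)
}

test_that("stratified k-NN imputation matches a brute-force neighbour oracle", {
  # one stratum of 4 subjects, 2 features, 1 missing cell in f1 of s4;
  # a wildly different out-of-stratum donor must never be consulted
  vals <- rbind(f1 = c(1, 2, 3, NA, 500),
                f2 = c(10, 11, 12, 10.1, 900))
  sev <- c("non", "non", "non", "non", "severe")
  tab <- toyTable(vals, sev)
  out <- stratifiedKnnImpute(tab, k = 3L)
  # oracle: distances to s4 within stratum use the complete feature f2,
  # standardized within the stratum; 3 nearest of 3 donors -> mean(f1)
  expect_equal(featureValues(out)["f1", 4], mean(c(1, 2, 3)))
  expect_false(any(missingMask(out)))
  # k = 1: nearest donor by |f2 - 10.1| is s1 (f2 = 10)
  out1 <- stratifiedKnnImpute(tab, k = 1L)
  expect_equal(featureValues(out1)["f1", 4], 1)
  # untouched cells unchanged; imputation idempotent
  expect_equal(featureValues(out)["f2", ], featureValues(tab)["f2", ])
  expect_identical(featureValues(stratifiedKnnImpute(out)), featureValues(out))
})

test_that("imputation falls back to the stratum mean for tiny strata", {
  vals <- rbind(f1 = c(1, NA, 7, 9), f2 = c(2, 3, 8, 10))
  tab <- toyTable(vals, c("mild", "mild", "severe", "severe"))
  expect_warning(out <- stratifiedKnnImpute(tab, k = 3L), "stratum")
  expect_equal(featureValues(out)["f1", 2], 1)  # mean of the one mild donor
})

test_that("a complete table passes through imputation unchanged", {
  tab <- featureCohort()
  expect_identical(stratifiedKnnImpute(tab), tab)
})

test_that("plug-in mutual information matches direct evaluation", {
  # deterministic function of 4 equiprobable labels -> MI = H(Y) = 2 bits
  y <- rep(c("a", "b", "c", "d"), each = 50)
  x <- rep(c(0, 1, 2, 3), each = 50) + runif(200, 0, 0.1)
  expect_equal(mutualInformation(x, y, bins = 4), 2, tolerance = 1e-10)
  # hand-computable 2-bin/2-class joint table: counts ((30,10),(10,30))
  x2 <- c(rep(0, 40), rep(1, 40))
  y2 <- c(rep("p", 30), rep("q", 10), rep("p", 10), rep("q", 30))
  pj <- c(30, 10, 10, 30) / 80
  mi <- sum(pj * log2(pj / c(0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5)))
  expect_equal(mutualInformation(x2, y2, bins = 2), mi, tolerance = 1e-10)
  # independence: an independent feature's MI is indistinguishable from the
  # permutation null (the plug-in estimator has a positive finite-sample bias,
  # about (bins-1)(classes-1)/(2 n ln 2) bits, shared by the null)
  set.seed(4)
  xi <- rnorm(199)
  yi <- sample(severityLevels(), 199, replace = TRUE)
  obs <- mutualInformation(xi, yi, bins = 10)
  null <- replicate(200, mutualInformation(xi, sample(yi), bins = 10))
  expect_lt(obs, quantile(null, 0.99))
  expect_lt(abs(obs - mean(null)), 4 * sd(null))
})

test_that("adaptive normalization stores train-fitted schemes and flags constants", {
  set.seed(5)
  n <- 120
  sev <- rep(severityLevels(), each = n / 4)
  vals <- rbind(gauss = rnorm(n, 50, 10),
                outliery = c(rnorm(n - 5, 0, 1), rep(80, 5)),
                constant = rep(3, n))
  tab <- toyTable(vals, sev)
  out <- adaptiveNormalize(tab, bins = 8)
  meta <- S4Vectors::metadata(out)$norm_meta
  # equal-frequency binning makes monotone schemes tie -> preference order wins
  expect_equal(meta$gauss$scheme, "zscore")
  expect_true(meta$constant$flagged)
  expect_equal(featureValues(out)["constant", ], featureValues(tab)["constant", ])
  # train-only fitting: applying stored params to held-out columns row-wise
  trainIdx <- seq_len(80)
  fit <- adaptiveNormalize(tab, trainIdx = trainIdx)
  reapplied <- applyNormalization(tab, S4Vectors::metadata(fit)$norm_meta)
  expect_equal(featureValues(reapplied), featureValues(fit))
  perRow <- applyNormalization(tab[, 81:120], S4Vectors::metadata(fit)$norm_meta)
  expect_equal(featureValues(perRow), featureValues(fit)[, 81:120])
})

test_that("the t-test filter is calibrated for null and shifted features", {
  set.seed(6)
  y <- rep(c("a", "b"), each = 30)
  reps <- 200
  keptNull <- 0; keptShift <- 0
  for (r in seq_len(reps)) {
    X <- cbind(null = rnorm(60), shift = c(rnorm(30), rnorm(30, 2)))
    kept <- ttestFilter(X, y, alpha = 0.05)
    keptNull <- keptNull + ("null" %in% kept)
    keptShift <- keptShift + ("shift" %in% kept)
  }
  # type-I: null feature kept with probability about alpha
  expect_lt(keptNull / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  # power: a 2-SD shift at n = 30/class is essentially always kept
  expect_gt(keptShift / reps, 0.99)
  # zero-variance-in-both-classes feature is removed by convention
  Xz <- cbind(flat = rep(1, 60), ok = c(rnorm(30), rnorm(30, 3)))
  expect_false("flat" %in% ttestFilter(Xz, y))
})

test_that("SHAP ranking puts a perfectly separating feature first", {
  set.seed(7)
  n <- 80
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("noise%02d", 1:10)))
  X <- cbind(X, signal = ifelse(y == "b", 2, -2) + rnorm(n, 0, 0.1))
  r <- shapRank(X, y, colnames(X), seed = 3)
  expect_identical(names(r)[1], "signal")
  expect_setequal(names(r), colnames(X))
  # duplicated feature pair: attribution splits, combined share stays high
  X2 <- cbind(X, signal_copy = X[, "signal"])
  r2 <- shapRank(X2, y, colnames(X2), seed = 3)
  pair <- r2[c("signal", "signal_copy")]
  expect_gt(sum(pair) / sum(r2), 0.5)
})

test_that("RUSBoost separates and undersamples; RFE recovers informative features", {
  set.seed(8)
  n1 <- 60; n2 <- 20  # imbalanced
  y <- c(rep("maj", n1), rep("min", n2))
  X <- rbind(matrix(rnorm(n1 * 4), n1, 4), matrix(rnorm(n2 * 4, 2.5), n2, 4))
  colnames(X) <- paste0("f", 1:4)
  m <- rusboostFit(X, y, seed = 2)
  expect_gt(balancedAccuracy(rusboostPredict(m, X), y), 0.9)
  p <- rusboostPredict(m, X, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
  # RFE: 5 informative among 25 noise features
  set.seed(9)
  n <- 90
  y2 <- rep(c("a", "b"), length.out = n)
  inf <- sapply(1:5, function(i) ifelse(y2 == "b", 1.8, -1.8) + rnorm(n, 0, 0.8))
  noise <- matrix(rnorm(n * 25), n, 25)
  X2 <- cbind(inf, noise)
  colnames(X2) <- c(sprintf("inf%d", 1:5), sprintf("noise%02d", 1:25))
  ranked <- names(shapRank(X2, y2, colnames(X2), seed = 4))
  rep <- rfeSelect(X2, y2, ranked, targetK = 8L, anthro = character(0), seed = 5)
  expect_length(rep$final_selected, 8)
  expect_gte(sum(sprintf("inf%d", 1:5) %in% rep$final_selected), 4)
  # identity when targetK equals the ranked size
  repAll <- rfeSelect(X2, y2, ranked, targetK = length(ranked),
                      anthro = character(0), seed = 5)
  expect_setequal(repAll$final_selected, ranked)
})

test_that("per-task selection yields the 30 + 5 design and nested stages", {
  ft <- adaptiveNormalize(featureCohort(effect = 3, seed = 19,
                                        sizes = c(non = 25, mild = 25, moderate = 25, severe = 25)))
  rep <- selectTaskFeatures(ft, c("non", "severe"), targetK = 10L, seed = 6)
  expect_length(rep$final_selected, 10)
  expect_length(rep$design_features, 15)
  expect_true(all(rep$final_selected %in% names(rep$stage2_ranking)))
  expect_true(all(names(rep$stage2_ranking) %in% rep$stage1_kept))
  expect_true(all(c("age", "sex", "bmi", "nc", "mps") %in% rep$design_features))
  expect_false(any(c("age", "sex", "bmi", "nc", "mps") %in% rep$final_selected))
})
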
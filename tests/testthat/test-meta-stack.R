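metaFixture <- function() fixture("metaFixture", function() {
  tab <- featureCohort(effect = 3, seed = 23,
                       sizes = c(non = 30, mild = 24, moderate = 24, severe = 24))
  sp <- stratifiedSplit(osascreen:::subjectTableFromFeatures(tab), 0.2,
                        seed = 2, swaps = 0L)
  bundle <- trainOvoBundle(tab, subjects = sp$train, candidates = "logistic",
                           B = 12L, budget = 1L, seed = 3)
  list(tab = tab, sp = sp, bundle = bundle)
})

test_that("class schemes map severities correctly", {
  s3 <- classScheme("three"); s4 <- classScheme("four")
  expect_identical(s3$classes, c("non", "mild", "moderate_severe"))
  expect_identical(s4$classes, severityLevels())
  expect_identical(applyScheme(c("moderate", "severe", "non"), s3),
                   c("moderate_severe", "moderate_severe", "non"))
  expect_identical(applyScheme(severityLevels(), s4), severityLevels())
})

test_that("meta features are 12 columns with complementary pairs and OOB control", {
  fx <- metaFixture()
  mX <- buildMetaFeatures(fx$bundle, fx$tab, fx$sp$train, useOob = TRUE)
  expect_equal(ncol(mX), 12)
  for (t in seq_len(6)) {
    pairSum <- rowSums(mX[, c(2 * t - 1, 2 * t)])
    expect_equal(pairSum, rep(1, nrow(mX)), tolerance = 1e-9, ignore_attr = TRUE)
  }
  # OOB features differ from full-bag features on the bundle's own rows
  full <- buildMetaFeatures(fx$bundle, fx$tab, fx$sp$train, useOob = FALSE)
  expect_gt(max(abs(mX - full)), 1e-6)
  # unseen rows use the full bag (no OOB attribute requested)
  mTest <- buildMetaFeatures(fx$bundle, fx$tab, fx$sp$test)
  expect_equal(ncol(mTest), 12)
})

test_that("meta-model probabilities are valid and schemes set the width", {
  fx <- metaFixture()
  sev <- severityLabels(fx$tab)
  mX <- buildMetaFeatures(fx$bundle, fx$tab, fx$sp$train, useOob = TRUE)
  for (sn in c("three", "four")) {
    meta <- trainMeta(mX, sev[fx$sp$train], classScheme(sn),
                      candidates = "multinomial", seed = 4)
    p <- predictProba(meta, buildMetaFeatures(fx$bundle, fx$tab, fx$sp$test))
    expect_equal(ncol(p), if (sn == "three") 3 else 4)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(trainMeta(mX, rep("non", nrow(mX)), classScheme("four"),
                         candidates = "multinomial"), "degenerate")
})

test_that("stacking learns a separable cohort well above chance", {
  fx <- metaFixture()
  sev <- severityLabels(fx$tab)
  mX <- buildMetaFeatures(fx$bundle, fx$tab, fx$sp$train, useOob = TRUE)
  meta <- trainMeta(mX, sev[fx$sp$train], classScheme("four"),
                    candidates = "multinomial", seed = 5)
  pred <- predictClass(meta, buildMetaFeatures(fx$bundle, fx$tab, fx$sp$test))
  acc <- mean(pred == sev[fx$sp$test])
  expect_gt(acc, 0.6)  # chance would be ~0.29 at these class sizes
  # row permutation equivariance
  mTest <- buildMetaFeatures(fx$bundle, fx$tab, fx$sp$test)
  perm <- sample(nrow(mTest))
  expect_equal(unname(predictProba(meta, mTest[perm, ])),
               unname(predictProba(meta, mTest)[perm, ]))
})

test_that("the MLP learner fits multi-class structure and respects its defaults", {
  set.seed(6)
  n <- 240
  y <- rep(c("a", "b", "c"), each = n / 3)
  X <- cbind(x1 = rnorm(n) + c(a = -2, b = 0, c = 2)[y],
             x2 = rnorm(n) + c(a = 0, b = 2, c = -2)[y])
  m <- mlpFit(X, y, hidden = c(16L, 16L), lr = 0.02, epochs = 150, seed = 7)
  p <- mlpPredict(m, X)
  expect_equal(dim(p), c(n, 3))
  expect_equal(rowSums(p), rep(1, n), tolerance = 1e-9, ignore_attr = TRUE)
  expect_gt(mean(colnames(p)[max.col(p)] == y), 0.85)
  # scheme-specific defaults: depth and learning rate
  fam3 <- osascreen:::.metaFamilies(classScheme("three"), 1L)
  fam4 <- osascreen:::.metaFamilies(classScheme("four"), 1L)
  m3 <- environment(fam3$mlp$fit)
  expect_equal(environment(fam3$mlp$fit)$hidden, c(16L, 16L))
  expect_equal(environment(fam3$mlp$fit)$lr, 7.06e-2)
  expect_equal(environment(fam4$mlp$fit)$hidden, c(16L, 16L, 8L))
  expect_equal(environment(fam4$mlp$fit)$lr, 5.14e-3)
})
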
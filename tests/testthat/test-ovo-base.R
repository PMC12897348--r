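test_that("task enumeration gives all canonical pairs", {
  t4 <- enumerateTasks()
  expect_length(t4, 6)
  expect_identical(t4[[1]], c("non", "mild"))
  expect_identical(t4[[6]], c("moderate", "severe"))
  expect_length(enumerateTasks(c("a", "b", "c")), 3)
  expect_length(enumerateTasks(c("a", "b")), 1)
  expect_error(enumerateTasks("a"))
})

test_that("a linearly separable task is learned with high OOB accuracy", {
  set.seed(1)
  n <- 60
  X <- rbind(matrix(rnorm(n * 3, 0), n, 3), matrix(rnorm(n * 3, 4), n, 3))
  colnames(X) <- paste0("f", 1:3)
  y <- rep(c("non", "severe"), each = n)
  m <- trainBase(X, y, candidates = "logistic", B = 20L, budget = 1L, seed = 2)
  expect_gt(m$oob$balanced_accuracy, 0.95)
  expect_identical(m$classes, c("non", "severe"))
  # determinism
  m2 <- trainBase(X, y, candidates = "logistic", B = 20L, budget = 1L, seed = 2)
  expect_equal(m$oob$prob, m2$oob$prob)
})

test_that("OOB accuracy is at chance when classes are identical in distribution", {
  set.seed(3)
  n <- 80
  X <- matrix(rnorm(2 * n * 4), 2 * n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("mild", "moderate"), each = n)
  m <- trainBase(X, y, candidates = "logistic", B = 20L, budget = 1L, seed = 4)
  # balanced accuracy within binomial noise of 0.5
  expect_lt(abs(m$oob$balanced_accuracy - 0.5), 3 * sqrt(0.25 / (2 * n)) + 0.05)
})

test_that("OOB scoring matches brute-force enumeration and never sees own rows", {
  set.seed(5)
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("f1", "f2")))
  y01 <- c(0, 1, 0, 1, 1)
  fam <- osascreen:::.baseFamilies()$logistic
  members <- osascreen:::.bagFit(X, y01, fam, list(), B = 3L, seed = 6)
  oob <- suppressWarnings(oobScores(members, "logistic", X))
  for (i in 1:5) {
    exc <- Filter(function(m) !(i %in% m$rows), members)
    if (!length(exc)) {
      expect_true(is.na(oob$prob[i]))
    } else {
      manual <- mean(vapply(exc, function(m)
        fam$prob(m$fit, X[i, , drop = FALSE]), numeric(1)))
      expect_equal(oob$prob[i], manual, tolerance = 1e-12)
      # index audit: no contributing member trained on row i
      expect_true(all(vapply(exc, function(m) !(i %in% m$rows), logical(1))))
    }
  }
  # B = 1: every in-bootstrap row is OOB-undefined
  m1 <- osascreen:::.bagFit(X, y01, fam, list(), B = 1L, seed = 7)
  oob1 <- suppressWarnings(oobScores(m1, "logistic", X))
  expect_true(all(is.na(oob1$prob[unique(m1[[1]]$rows)])))
})

test_that("the expected OOB-eligible member fraction approaches 1/e", {
  set.seed(8)
  n <- 100
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  y01 <- rep(c(0, 1), each = n / 2)
  fam <- osascreen:::.baseFamilies()$logistic
  B <- 60L
  members <- osascreen:::.bagFit(X, y01, fam, list(), B = B, seed = 9)
  oob <- suppressWarnings(oobScores(members, "logistic", X))
  expect_equal(mean(oob$nMembers) / B, exp(-1), tolerance = 0.05)
})

test_that("pair scores are 12 complementary probabilities in task order", {
  tab <- featureCohort()
  sp <- stratifiedSplit(osascreen:::subjectTableFromFeatures(tab), 0.2, seed = 1,
                        swaps = 0L)
  bundle <- trainOvoBundle(tab, subjects = sp$train, candidates = "logistic",
                           B = 8L, budget = 1L, seed = 10)
  expect_length(bundle@tasks, 6)
  sc <- predictPairScores(bundle, tab, sp$test)
  expect_equal(ncol(sc), 12)
  expect_true(all(sc >= 0 & sc <= 1))
  for (t in seq_len(6))
    expect_equal(rowSums(sc[, c(2 * t - 1, 2 * t)]), rep(1, nrow(sc)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  # determinism of the whole bundle
  b2 <- trainOvoBundle(tab, subjects = sp$train, candidates = "logistic",
                       B = 8L, budget = 1L, seed = 10)
  expect_equal(predictPairScores(b2, tab, sp$test), sc)
})

test_that("hyperparameter search improves or matches a default random forest", {
  set.seed(11)
  n <- 50
  X <- rbind(matrix(rnorm(n * 4), n, 4), matrix(rnorm(n * 4, 1.2), n, 4))
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c("non", "mild"), each = n)
  m <- trainBase(X, y, candidates = "randomForest", B = 10L, budget = 4L, seed = 12)
  expect_equal(m$family, "randomForest")
  expect_true(all(c("mtryFrac", "minNode") %in% names(m$params)))
  expect_equal(nrow(m$searchLog), 4)
  expect_gt(max(m$searchLog$score), 0.6)
})
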
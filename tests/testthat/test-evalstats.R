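test_that("confusion metrics match hand evaluation", {
  # toy 3-class confusion [[2,1,0],[0,2,0],[0,1,2]] (rows = truth)
  truths <- c(rep("a", 3), rep("b", 2), rep("c", 3))
  preds <- c("a", "a", "b", "b", "b", "b", "c", "c")
  ev <- confusionAndMetrics(preds, truths, c("a", "b", "c"))
  expect_equal(ev$accuracy, 100 * 6 / 8)
  expect_equal(ev$macro_sensitivity, 100 * mean(c(2 / 3, 1, 2 / 3)))
  expect_equal(sum(ev$confusion), 8)
  expect_equal(rowSums(ev$confusion), c(a = 3, b = 2, c = 3), ignore_attr = TRUE)
  # perfect predictions
  evP <- confusionAndMetrics(truths, truths, c("a", "b", "c"))
  expect_equal(evP$accuracy, 100)
  expect_equal(evP$macro_sensitivity, 100)
  expect_equal(evP$macro_specificity, 100)
  # chance level for independent predictions on 2 balanced classes
  set.seed(1)
  t2 <- rep(c("x", "y"), 2000)
  p2 <- sample(t2)
  expect_equal(confusionAndMetrics(p2, t2, c("x", "y"))$accuracy, 50, tolerance = 5)
  # absent class excluded from the macro average, with a warning
  expect_warning(evA <- confusionAndMetrics(c("a", "b"), c("a", "a"), c("a", "b")),
                 "absent")
  expect_equal(evA$macro_sensitivity, 50)
})

test_that("per-class AUC recovers known orderings", {
  set.seed(2)
  n <- 200
  truths <- rep(c("a", "b"), each = n / 2)
  scores <- cbind(a = c(rnorm(n / 2, 1), rnorm(n / 2)),
                  b = c(rnorm(n / 2), rnorm(n / 2, 1)))
  ev <- confusionAndMetrics(ifelse(scores[, "a"] > scores[, "b"], "a", "b"),
                            truths, c("a", "b"), scores = scores)
  expect_gt(ev$auc[["a"]], 0.7)
  expect_gt(ev$auc[["b"]], 0.7)
})

test_that("fold summaries use the sample standard deviation", {
  threeClass <- meanSdOverFolds(c(78.7, 78.8, 75.8))
  expect_equal(round(threeClass$mean, 1), 77.8)
  expect_equal(round(threeClass$sd, 1), 1.7)
  fourClass <- meanSdOverFolds(c(77.1, 75.6, 77.4))
  expect_equal(round(fourClass$mean, 1), 76.7)
  expect_equal(meanSdOverFolds(c(5, 5, 5))$sd, 0)
  expect_error(meanSdOverFolds(7), "at least 2")
})

test_that("bootstrap intervals behave on degenerate and Gaussian samples", {
  expect_equal(bootstrapCi(rep(3, 10)), c(3, 3))
  set.seed(3)
  x <- rnorm(100)
  ci <- bootstrapCi(x, B = 2000, seed = 4)
  expect_gte(mean(x), ci[1]); expect_lte(mean(x), ci[2])
  # width within 20% of the asymptotic 2 * 1.96 / sqrt(n)
  expect_equal(diff(ci), 2 * 1.96 * sd(x) / sqrt(100), tolerance = 0.2)
})

test_that("repeated trials aggregate deterministically over seed lists", {
  run <- function(seed) { set.seed(seed); c(acc = mean(rnorm(20, 0.7, 0.05))) }
  one <- repeatedTrials(run, nTrials = 1L, seeds = 42L)
  expect_equal(one$summary$mean, unname(run(42L)))
  r1 <- repeatedTrials(run, nTrials = 5L, baseSeed = 7)
  r2 <- repeatedTrials(run, nTrials = 5L, baseSeed = 7)
  expect_identical(r1$trials, r2$trials)
  r3 <- repeatedTrials(run, nTrials = 5L, baseSeed = 8)
  expect_false(identical(r1$trials, r3$trials))
  expect_equal(dim(r1$trials), c(5, 1))
})

test_that("paired comparison statistics match their closed-form oracles", {
  # Bonferroni threshold for the six base-model comparisons
  cc0 <- compareClassifiers(rep(1, 10), rep(1, 10), m = 6)
  expect_equal(cc0$bonferroni_alpha, 0.05 / 6)
  expect_equal(round(cc0$bonferroni_alpha, 5), 0.00833)
  # identical vectors: all null
  expect_true(cc0$degenerate)
  expect_equal(cc0$mean_delta_accuracy, 0)
  expect_equal(cc0$cohens_d, 0)
  expect_equal(cc0$cliffs_delta, 0)
  expect_equal(cc0$p_mcnemar, 1)
  # 9 discordant pairs all favouring A: exact binomial 2 * (1/2)^9
  a <- c(rep(1, 9), 1); b <- c(rep(0, 9), 1)
  cc <- compareClassifiers(a, b)
  expect_equal(cc$p_mcnemar, 2 * 0.5^9, tolerance = 1e-12)
  # Cliff's delta by exhaustive pair enumeration on a = (1,1,1,0), b = (0,0,1,1)
  a2 <- c(1, 1, 1, 0, 1); b2 <- c(0, 0, 1, 1, 0)  # n >= 5 for the tests
  brute <- (sum(outer(a2, b2, ">")) - sum(outer(a2, b2, "<"))) / 25
  expect_equal(compareClassifiers(a2, b2)$cliffs_delta, brute)
  # McNemar ignores concordant pairs
  ccPlus <- compareClassifiers(c(a, 1, 1, 1), c(b, 1, 1, 1))
  expect_equal(ccPlus$p_mcnemar, cc$p_mcnemar)
})

test_that("the paired t-test is type-I calibrated on identical coin flips", {
  set.seed(5)
  reps <- 600
  rej <- replicate(reps, {
    a <- rbinom(80, 1, 0.7); b <- rbinom(80, 1, 0.7)
    cc <- compareClassifiers(a, b)
    cc$p_ttest < 0.05
  })
  # within 3 binomial SEs of the nominal rate
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("learning curves improve with training fraction on a separable cohort", {
  tab <- featureCohort(effect = 3, seed = 29,
                       sizes = c(non = 40, mild = 30, moderate = 35, severe = 30))
  sp <- stratifiedSplit(osascreen:::subjectTableFromFeatures(tab), 0.2,
                        seed = 6, swaps = 0L)
  lc <- learningCurve(tab, sp$train, sp$test, fractions = c(0.3, 1.0),
                      scheme = "four", seeds = 1:2,
                      impute = FALSE, normalize = FALSE, select = FALSE,
                      candidates = "logistic", metaCandidates = "multinomial",
                      B = 8L, budget = 1L)
  expect_equal(nrow(lc), 4)
  expect_setequal(names(lc), c("fraction", "seed", "accuracy", "sensitivity",
                               "specificity"))
  agg <- tapply(lc$accuracy, lc$fraction, mean)
  expect_gte(agg[["1"]], agg[["0.3"]] - 5)  # monotone up to noise
})
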
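test_that("AHI maps to severity with left-closed clinical cut-offs", {
  expect_identical(severityFromAhi(1.18), "non")
  expect_identical(severityFromAhi(c(5, 14.99, 15, 29.99, 30, 120)),
                   c("mild", "mild", "moderate", "moderate", "severe", "severe"))
  expect_error(severityFromAhi(-0.1), "non-negative")
  expect_error(severityFromAhi(NA_real_), "non-negative")
})

test_that("generated cohorts match the requested class structure and are reproducible", {
  spec <- cohortSpec(classSizes = c(non = 5, mild = 4, moderate = 3, severe = 2), seed = 9)
  c1 <- generateCohort(spec, audio = FALSE)
  tab <- subjectTable(c1)
  expect_equal(unname(table(factor(tab$severity, levels = severityLevels()))[severityLevels()]),
               c(5, 4, 3, 2), ignore_attr = TRUE)
  # severity is always the image of AHI under the cut-offs
  expect_identical(severityFromAhi(tab$ahi), tab$severity)
  expect_true(all(tab$mps %in% 1:4))
  expect_true(all(tab$age > 0 & tab$bmi > 0 & tab$nc > 0))
  # determinism: same spec, same cohort
  c2 <- generateCohort(spec, audio = FALSE)
  expect_identical(subjectTable(c2), tab)
  # stability under class-size edits: shared subjects unchanged
  c3 <- generateCohort(cohortSpec(classSizes = c(non = 3, mild = 4, moderate = 3, severe = 2),
                                  seed = 9), audio = FALSE)
  t3 <- subjectTable(c3)
  expect_identical(t3[t3$severity == "mild", ], tab[tab$severity == "mild", ],
                   ignore_attr = TRUE)
})

test_that("default specification reproduces the reference class sizes", {
  spec <- cohortSpec()
  expect_equal(spec$classSizes, c(non = 74, mild = 35, moderate = 50, severe = 40))
  expect_equal(sum(spec$classSizes), 199)
})

test_that("per-class anthropometric means match their targets at large n", {
  sizes <- c(non = 74, mild = 35, moderate = 50, severe = 40) * 25L
  coh <- generateCohort(cohortSpec(classSizes = sizes, seed = 42), audio = FALSE)
  tab <- subjectTable(coh)
  pars <- osascreen:::.defaultAnthro()
  for (cl in severityLevels()) {
    sub <- tab[tab$severity == cl, ]
    for (v in c("age", "bmi", "nc")) {
      target <- pars[[cl]][[v]]
      se <- target[2] / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[v]]) - target[1]), 3 * se,
                label = sprintf("|%s %s mean - target|", cl, v))
    }
    expect_lt(abs(mean(sub$sex == "M") - pars[[cl]]$sex_m),
              3 * sqrt(0.25 / nrow(sub)))
  }
})

test_that("synthetic recordings contain the protocol's five breath cycles", {
  for (sev in c("non", "severe")) {
    rec <- synthBreathRecording(sev, "nose", 1, seed = 5, rate = 8000)
    expect_equal(countBreathCycles(rec), 5)
    expect_true(all(is.finite(rec@samples)))
  }
  r3 <- synthBreathRecording("mild", "mouth", 0, seed = 6, rate = 8000, cycles = 3)
  expect_equal(countBreathCycles(r3), 3)
})

test_that("missingness injection is MCAR on anthropometrics only, seeded, binomial", {
  tab <- featureCohort()
  expect_identical(injectMissingness(tab, 0), tab)
  m1 <- injectMissingness(tab, 0.1, seed = 3)
  m2 <- injectMissingness(tab, 0.1, seed = 3)
  expect_identical(missingMask(m1), missingMask(m2))
  acoustic <- featureFamily(tab) != "anthropometric"
  expect_false(any(missingMask(m1)[acoustic, ]))
  expect_error(injectMissingness(tab, 1), "rate")
  # masked-count within the binomial 99% interval over the eligible cells
  big <- simulateFeatureCohort(c(non = 50, mild = 50, moderate = 50, severe = 50),
                               seed = 8)
  mb <- injectMissingness(big, 0.1, seed = 4)
  nCells <- 5L * 200L
  hits <- sum(missingMask(mb))
  expect_gte(hits, qbinom(0.005, nCells, 0.1))
  expect_lte(hits, qbinom(0.995, nCells, 0.1))
})

test_that("zero acoustic effect size removes class separability of features", {
  tabs <- lapply(c(0, 3), function(es)
    simulateFeatureCohort(c(non = 60, mild = 0, moderate = 0, severe = 60),
                          effectSize = es, seed = 13))
  aucOf <- function(tab) {
    v <- featureValues(tab)["acoustic_001", ]
    y <- severityLabels(tab) == "severe"
    mean(outer(v[y], v[!y], ">")) # rank separability of one informative feature
  }
  expect_lt(abs(aucOf(tabs[[1]]) - 0.5), 0.1)
  expect_gt(abs(aucOf(tabs[[2]]) - 0.5), 0.25)
})
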
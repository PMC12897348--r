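# Minimal subject frame (severity + balancing covariates) from a FeatureTable.
subjectTableFromFeatures <- function(table) {
  v <- featureValues(table)
  an <- intersect(c("age", "sex", "bmi", "nc", "mps"), rownames(v))
  df <- data.frame(subject_id = colnames(v), severity = severityLabels(table))
  for (f in an) df[[f]] <- v[f, ]
  if (is.numeric(df$sex)) df$sex <- ifelse(df$sex >= 0.5, "M", "F")
  df
}

#' Stratified train/test split with covariate balancing
#'
#' Per severity class, the test count is the nearest integer to
#' `testFraction` times the class size (half rounded up); membership is
#' randomized under the seed, then refined by greedy same-class swaps that
#' reduce the train/test discrepancy in age, BMI and neck-circumference
#' means and in sex and Mallampati proportions.
#'
#' @param subjects data.frame with `severity` and (optionally) `age, bmi,
#'   nc, sex, mps` columns, or a [SoundCohort-class]
#' @param testFraction fraction in (0, 1), default 0.15
#' @param seed integer seed
#' @param swaps number of greedy swap attempts (0 disables balancing)
#' @return List with integer row indices `train` and `test`.
#' @export
stratifiedSplit <- function(subjects, testFraction = 0.15, seed = 1L, swaps = 200L) {
  if (is(subjects, "SoundCohort")) subjects <- subjectTable(subjects)
  stopifnot(testFraction > 0, testFraction < 1)
  sev <- subjects$severity
  test <- integer(0)
  withSeed(seed, {
    for (cl in unique(sev)) {
      ix <- which(sev == cl)
      if (length(ix) < 2L) {
        warning("class '", cl, "' too small to split; all rows to train")
        next
      }
      nTest <- floor(testFraction * length(ix) + 0.5)
      if (nTest > 0L) test <- c(test, sample(ix, nTest))
    }
    if (swaps > 0L) {
      disc <- function(testIdx) {
        trainIdx <- setdiff(seq_len(nrow(subjects)), testIdx)
        d <- 0
        for (v in intersect(c("age", "bmi", "nc"), colnames(subjects))) {
          x <- subjects[[v]]
          ok <- !is.na(x)
          d <- d + abs(mean(x[intersect(trainIdx, which(ok))]) -
                       mean(x[intersect(testIdx, which(ok))])) / (stats::sd(x[ok]) + 1e-9)
        }
        if ("sex" %in% colnames(subjects))
          d <- d + abs(mean(subjects$sex[trainIdx] == "M", na.rm = TRUE) -
                       mean(subjects$sex[testIdx] == "M", na.rm = TRUE))
        if ("mps" %in% colnames(subjects))
          for (m in 1:4)
            d <- d + abs(mean(subjects$mps[trainIdx] == m, na.rm = TRUE) -
                         mean(subjects$mps[testIdx] == m, na.rm = TRUE))
        d
      }
      cur <- disc(test)
      for (s in seq_len(swaps)) {
        cl <- sample(unique(sev), 1L)
        inT <- intersect(test, which(sev == cl))
        outT <- setdiff(which(sev == cl), test)
        if (!length(inT) || !length(outT)) next
        cand <- test
        cand[cand == sample(inT, 1L)] <- sample(outT, 1L)
        new <- disc(cand)
        if (new < cur) { test <- cand; cur <- new }
      }
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_len(nrow(subjects)), test), test = test)
}

#' Binary anthropometric factors for fold balancing
#'
#' Dichotomizes the balancing covariates at the clinical thresholds:
#' age >= 50, BMI >= 35, NC > 40, sex = M; the Mallampati score stays a
#' 4-level categorical. Missing values give `NA` (subject excluded from
#' that factor's balancing).
#'
#' @param subjects data.frame with `age, bmi, nc, sex, mps`
#' @return data.frame of logical factors plus `mps` as factor.
#' @export
binarizeFactors <- function(subjects) {
  data.frame(
    age_ge50 = subjects$age >= 50,
    bmi_ge35 = subjects$bmi >= 35,
    nc_gt40 = subjects$nc > 40,
    sex_m = subjects$sex == "M",
    mps = factor(subjects$mps, levels = 1:4)
  )
}

# Weighted imbalance objective of a fold assignment (lower is better):
# severity counts (weight 10) + binary factor proportions (weight 1 each).
kfoldObjective <- function(assignment, severity, factors, k) {
  obj <- 0
  for (cl in unique(severity)) {
    cnt <- tabulate(assignment[severity == cl], k)
    obj <- obj + 10 * stats::var(cnt)
  }
  for (f in c("age_ge50", "bmi_ge35", "nc_gt40", "sex_m")) {
    x <- factors[[f]]
    pr <- vapply(seq_len(k), function(fd) mean(x[assignment == fd], na.rm = TRUE), numeric(1))
    pr[!is.finite(pr)] <- 0
    obj <- obj + stats::var(pr)
  }
  for (m in levels(factors$mps)) {
    pr <- vapply(seq_len(k), function(fd) mean(factors$mps[assignment == fd] == m,
                                               na.rm = TRUE), numeric(1))
    pr[!is.finite(pr)] <- 0
    obj <- obj + stats::var(pr) / 4
  }
  obj
}

#' Joint severity-by-anthropometric stratified k-fold assignment
#'
#' Greedy constrained assignment: subjects are ordered by the rarity of
#' their joint (severity x binarized-factor) cell, then each is assigned
#' to the fold that minimizes a weighted imbalance objective (severity
#' counts weighted 10, each factor proportion 1), under the hard
#' constraint that per-class fold counts never exceed `ceiling(n_c / k)` —
#' which pins per-class fold sizes within 1 of each other. When `k`
#' exceeds the smallest class size the hard constraint is infeasible for
#' that class and is relaxed with a warning.
#'
#' @param subjects data.frame with `severity, age, bmi, nc, sex, mps`, or a
#'   [SoundCohort-class]
#' @param k number of folds (>= 2)
#' @param seed integer seed (tie-breaking order)
#' @return List with `assignment` (fold index per subject), `k`, and
#'   `audit` (per-fold severity counts and factor proportions).
#' @export
jointStratifiedKfold <- function(subjects, k = 3L, seed = 1L) {
  if (is(subjects, "SoundCohort")) subjects <- subjectTable(subjects)
  stopifnot(k >= 2L)
  sev <- subjects$severity
  if (k > min(table(sev)))
    warning("k exceeds the smallest class; per-class balance relaxed to best effort")
  fac <- binarizeFactors(subjects)
  cell <- paste(sev, fac$age_ge50, fac$bmi_ge35, fac$nc_gt40, fac$sex_m, fac$mps)
  rarity <- table(cell)[cell]
  ord <- withSeed(seed, order(rarity, stats::runif(length(cell))))
  n <- length(sev)
  assignment <- integer(n)
  classCap <- ceiling(table(sev) / k)
  for (i in ord) {
    allowed <- which(vapply(seq_len(k), function(fd)
      sum(sev[assignment == fd] == sev[i]) < classCap[[sev[i]]], logical(1)))
    if (!length(allowed)) allowed <- seq_len(k)
    best <- allowed[1]; bestObj <- Inf
    for (fd in allowed) {
      trial <- assignment; trial[i] <- fd
      o <- kfoldObjective(trial[trial > 0], sev[trial > 0], fac[trial > 0, ], k)
      if (o < bestObj) { bestObj <- o; best <- fd }
    }
    assignment[i] <- best
  }
  audit <- list(
    severity = t(vapply(seq_len(k), function(fd)
      table(factor(sev[assignment == fd], levels = unique(sev))),
      integer(length(unique(sev))))),
    objective = kfoldObjective(assignment, sev, fac, k)
  )
  list(assignment = assignment, k = k, audit = audit)
}
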
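rate <- 8000

test_that("normalized spectral entropy separates broadband noise from tones", {
  set.seed(2)
  white <- spectralFeatures(rnorm(2 * rate), rate)
  expect_gt(white[["sp_entropy"]], 0.95)
  tone <- spectralFeatures(sin(2 * pi * 440 * seq_len(2 * rate) / rate), rate)
  expect_lt(tone[["sp_entropy"]], 0.3)
})

test_that("sub-band powers partition the in-band total", {
  set.seed(3)
  for (x in list(rnorm(rate), sin(2 * pi * 800 * seq_len(rate) / rate) + 0.1 * rnorm(rate))) {
    f <- spectralFeatures(x, rate)
    bands <- f[grep("^sp_power_b", names(f))]
    expect_equal(sum(bands), f[["sp_total"]], tolerance = 1e-8, ignore_attr = TRUE)
  }
  short <- spectralFeatures(rnorm(100), rate)
  expect_true(all(is.na(short)))
})

test_that("bicoherence detects quadratic phase coupling and its absence", {
  nfft <- 128L; nSeg <- 80L
  i1 <- 12L; i2 <- 20L  # frequency bins of the coupled triad
  buildTriad <- function(coupled, seed) {
    set.seed(seed)
    unlist(lapply(seq_len(nSeg), function(s) {
      t <- 0:(nfft - 1L)
      p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
      p3 <- if (coupled) p1 + p2 else runif(1, 0, 2 * pi)
      cos(2 * pi * i1 * t / nfft + p1) + cos(2 * pi * i2 * t / nfft + p2) +
        cos(2 * pi * (i1 + i2) * t / nfft + p3)
    }))
  }
  est <- bispectrumEstimate(buildTriad(TRUE, 4), nfft = nfft, overlap = 0)
  expect_gt(est$b2[i1 + 1L, i2 + 1L], 0.8)
  est0 <- bispectrumEstimate(buildTriad(FALSE, 5), nfft = nfft, overlap = 0)
  expect_lt(est0$b2[i1 + 1L, i2 + 1L], 0.3)
  # estimator symmetry on the grid: B(f1, f2) = B(f2, f1)
  expect_equal(est$B[i1 + 1L, i2 + 1L], est$B[i2 + 1L, i1 + 1L], tolerance = 1e-10)
  off <- which(!is.na(est$B), arr.ind = TRUE)
  expect_equal(est$B[off], est$B[off[, 2:1]], tolerance = 1e-10)
})

test_that("fractal dimensions hit their known limits", {
  expect_lt(higuchiFd(seq(0, 1, length.out = 2000)), 1.1)
  expect_gte(higuchiFd(seq(0, 1, length.out = 2000)), 0.95)
  set.seed(6)
  fdNoise <- higuchiFd(rnorm(4000))
  expect_gt(fdNoise, 1.8); expect_lt(fdNoise, 2.05)
  expect_true(is.na(higuchiFd(rep(1, 1000))))
  expect_true(is.na(katzFd(rep(0, 100))))
})

test_that("zero-crossing rate of a tone follows the closed form", {
  f <- 325
  x <- sin(2 * pi * f * seq_len(2 * rate) / rate)
  tf <- timeFeatures(x, rate)
  expect_equal(tf[["td_zcr"]], 2 * f / rate, tolerance = 0.01)
})

test_that("Symlet-4 DWT conserves energy and localizes tones in sub-bands", {
  set.seed(8)
  x <- rnorm(4096)
  dw <- dwtSym4(x, 4L)
  expect_equal(sum(vapply(dw, function(c) sum(c^2), numeric(1))), sum(x^2),
               tolerance = 1e-9)
  # a tone in the middle of D2's range (rate/8 .. rate/4 -> 1000-2000 at 8 kHz)
  tone <- sin(2 * pi * 1500 * seq_len(4096) / rate)
  dwT <- dwtSym4(tone, 4L)
  en <- vapply(dwT, function(c) sum(c^2), numeric(1))
  expect_gt(en[["D2"]] / sum(en), 0.8)
  # silence: energies degenerate to explicit missing, never spurious values
  tfz <- tfFeatures(rep(0, 4096), rate)
  ez <- tfz[grep("energy", names(tfz))]
  expect_true(all(ez == 0 | is.na(ez)))
})

test_that("RQA and Lyapunov features distinguish periodic from stochastic dynamics", {
  t <- seq_len(600)
  sine <- sin(2 * pi * t / 25)
  r <- rqa(sine)
  expect_gt(r$det, 0.95)
  expect_equal(r$rr, 0.1, tolerance = 0.03)
  expect_null(rqa(rep(1, 600)))
  set.seed(9)
  lyNoise <- lyapunovRosenstein(rnorm(600))
  lySine <- lyapunovRosenstein(sine)
  expect_gt(lyNoise, lySine)
  expect_true(all(is.na(nonlinearFeatures(rep(2, 1000)))))
})

test_that("jitter and shimmer reproduce their closed forms on burst trains", {
  mkTrain <- function(periods, amps) {
    x <- numeric(round(sum(periods) * rate) + rate)
    pos <- cumsum(c(0.25, periods[-length(periods)]))
    for (i in seq_along(pos)) {
      n0 <- round(pos[i] * rate)
      burst <- amps[i] * sin(2 * pi * 500 * seq_len(0.08 * rate) / rate)
      x[n0 + seq_along(burst)] <- burst
    }
    x
  }
  # perfectly periodic: zero jitter and shimmer
  p0 <- perturbationFeatures(mkTrain(rep(0.6, 6), rep(1, 6)), rate)
  expect_equal(p0[["pt_jitter"]], 0, tolerance = 1e-6)
  expect_lt(p0[["pt_shimmer"]], 0.02)
  # alternating periods T, 1.1 T: jitter = 0.1/1.05
  pj <- perturbationFeatures(mkTrain(rep(c(0.6, 0.66), 4), rep(1, 8)), rate)
  expect_equal(pj[["pt_jitter"]], 0.1 / 1.05, tolerance = 0.02)
  # alternating amplitudes A, 1.2 A: shimmer = 0.2/1.1
  ps <- perturbationFeatures(mkTrain(rep(0.6, 8), rep(c(1, 1.2), 4)), rate)
  expect_equal(ps[["pt_shimmer"]], 0.2 / 1.1, tolerance = 0.02)
  # < 3 cycles -> missing
  expect_true(all(is.na(perturbationFeatures(mkTrain(0.6, 1), rate))))
})

test_that("scale-invariant features ignore amplitude; band powers scale quadratically", {
  seg <- segmentedRecording()
  ph <- seg$phases
  x <- seg$rec@samples[(ph$start_sample[1] + 1):ph$end_sample[1]]
  f1 <- phaseFeatures(x, rate)
  f3 <- phaseFeatures(3 * x, rate)
  inv <- c("sp_entropy", "hos_bicoh_mean", "td_higuchi", "td_zcr",
           "nl_rr", "nl_det", grep("tf_wav_energy", names(f1), value = TRUE))
  for (nm in inv)
    expect_equal(f3[[nm]], f1[[nm]], tolerance = 0.02, label = nm)
  for (nm in grep("sp_power", names(f1), value = TRUE))
    expect_equal(f3[[nm]] / f1[[nm]], 9, tolerance = 1e-6, label = nm)
})

test_that("aggregation is a per-feature mean with missing propagation", {
  v1 <- c(a = 1, b = 2, c = NA)
  v2 <- c(a = -1, b = 4, c = NA)
  expect_equal(aggregateSubject(list(v1)), v1)
  agg <- aggregateSubject(list(v1, v2))
  expect_equal(agg[["a"]], 0); expect_equal(agg[["b"]], 3)
  expect_true(is.na(agg[["c"]]))
  expect_equal(aggregateSubject(list(v2, v1)), agg)
})

test_that("the extracted feature table is finite with explicit missingness", {
  ft <- audioFeatures()
  v <- featureValues(ft)
  expect_false(any(is.nan(v)))
  expect_true(all(is.finite(v) | missingMask(ft)))
  expect_setequal(unique(featureFamily(ft)),
                  c("spectral", "hos", "time", "tf", "nonlinear",
                    "perturbation", "anthropometric"))
  expect_equal(anthropometricFeatures(ft), c("age", "sex", "bmi", "nc", "mps"))
  expect_false(anyDuplicated(rownames(ft)) > 0)
  # route x phase structure in the dictionary
  expect_true(all(c("nose_insp_sp_entropy", "mouth_exp_nl_det", "nose_pt_jitter")
                  %in% rownames(ft)))
})
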
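# Shared fixtures, built once per test run. Audio fixtures use an 8 kHz
# sampling rate to keep the suite fast; the analysis band (75-3000 Hz)
# still fits below Nyquist.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A small audio cohort (3 subjects/class) with strong class separation.
audioCohort <- function() fixture("audioCohort", function() {
  generateCohort(cohortSpec(classSizes = c(non = 3, mild = 3, moderate = 3, severe = 3),
                            rate = 8000, acousticEffectSize = 2, seed = 101))
})

audioFeatures <- function() fixture("audioFeatures", function() {
  extractFeatures(audioCohort())
})

# Feature-level cohorts for the modelling stack.
featureCohort <- function(effect = 2, seed = 11,
                          sizes = c(non = 30, mild = 20, moderate = 25, severe = 20)) {
  key <- paste0("fc_", effect, "_", seed, "_", paste(sizes, collapse = "-"))
  fixture(key, function() simulateFeatureCohort(sizes, effectSize = effect, seed = seed))
}

# One band-passed recording + its phases, reused across feature tests.
segmentedRecording <- function() fixture("segRec", function() {
  rec <- synthBreathRecording("moderate", "nose", 1, seed = 33, rate = 8000)
  bp <- bandpassBreath(rec)
  list(rec = bp, phases = logvarSegment(bp))
})

# Amplitude of a steady sine in a (possibly filtered) signal, measured by
# projection onto the quadrature pair over the central half of the signal.
sineAmplitude <- function(x, f, rate) {
  n <- length(x)
  mid <- seq(round(n / 4), round(3 * n / 4))
  t <- (mid - 1) / rate
  2 * sqrt(mean(x[mid] * sin(2 * pi * f * t))^2 +
           mean(x[mid] * cos(2 * pi * f * t))^2)
}
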
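# Shared expensive fixtures: the 40-patient synthetic cohorts (null and
# planted-signal) used by the calibration checks. Built once per test run
# and cached across test files.

.demo_cache <- new.env(parent = emptyenv())

demo_cohort <- function(effect_size, seed = 1L) {
  key <- sprintf("e%s_s%d", effect_size, seed)
  if (is.null(.demo_cache[[key]])) {
    cfg <- cohort_config(n_patients = 40L, frac_nondf = 12 / 43,
                         effect_size = effect_size, seed = seed)
    cohort <- generate_cohort(cfg)
    features <- suppressWarnings(
      build_cohort_features(cohort, list(feature_backend("toy"))))
    .demo_cache[[key]] <- list(cohort = cohort, features = features)
  }
  .demo_cache[[key]]
}

# Small fast cohort for structural pipeline tests.
tiny_cohort <- function(n = 8L, seed = 11L, effect_size = 1.5,
                        slide_px = 448L) {
  cohort_config(n_patients = n, frac_nondf = 0.25, effect_size = effect_size,
                slide_px = slide_px, seed = seed)
}
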
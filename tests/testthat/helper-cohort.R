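# Shared small synthetic cohorts, built once per test run.

.test_cache <- new.env(parent = emptyenv())

# sizes chosen so the whole suite stays fast: short recordings saturate the
# m = 2 entropy estimates and the band filters while keeping the quadratic
# template matching cheap
test_synth_config <- function(...) {
  args <- utils::modifyList(
    list(sampling_rate = 100, duration = 5, seed = 2024),
    list(...)
  )
  do.call(synthetic_config, args)
}

cached <- function(key, expr) {
  if (!exists(key, .test_cache)) assign(key, force(expr), .test_cache)
  get(key, .test_cache)
}

small_cohort <- function() {
  cached("small_cohort", generate_cohort(test_synth_config(n_subjects = 3)))
}

small_features <- function() {
  cached("small_features", suppressMessages(extract_features(small_cohort())))
}

# a 10-subject null cohort with its feature table, reused by several tests
null_cohort_features <- function() {
  cached("null_features", {
    cohort <- generate_cohort(test_synth_config(n_subjects = 10, seed = 77))
    suppressMessages(extract_features(cohort))
  })
}
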
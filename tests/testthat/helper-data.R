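# Shared small fixtures, generated once per test session.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(3, 3, 2, seed = 42)
    cache
  }
})

small_cycles <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- insoleCG:::cycles_for_model(preprocess_cohort(small_cohort()))
    cache
  }
})

# noise-free variant for exact structural checks
clean_cycles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(3, 3, 2, seed = 42, noise_scale = 0)
      cache <<- insoleCG:::cycles_for_model(preprocess_cohort(cohort))
    }
    cache
  }
})

# distance of each misclassified frame to the nearest phase boundary
boundary_distance <- function(pred, truth) {
  err <- which(pred != truth)
  if (!length(err)) return(0)
  b <- which(diff(truth) != 0)
  max(vapply(err, function(f) min(c(abs(f - b), abs(f - (b + 1)))), numeric(1)))
}
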
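# Shared fixtures: small simulation configs and a random closed
# composition generator.

small_config <- function(panel = "igg", n1 = c(20, 20), n0 = c(20, 20),
                         effect_map = c(), smoking_effect_map = c(),
                         seed = 42, n_batches_per_cohort = 2, ...) {
  sim_config(n_cases_per_cohort = n1, n_controls_per_cohort = n0,
             panel = panel,
             n_batches_per_cohort = n_batches_per_cohort,
             effect_map = effect_map,
             smoking_effect_map = smoking_effect_map, seed = seed, ...)
}

# random strictly-positive compositions closed to 100
random_composition <- function(n, panel, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n * length(peak_names(panel)), shape = 2), n)
    colnames(m) <- peak_names(panel)
    100 * m / rowSums(m)
  })
}

# linear ladder: rt = 2 + gu, for closed-form GU checks
linear_ladder <- function(K = 10) data.frame(gu = 1:K, rt = 2 + 1:K)
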
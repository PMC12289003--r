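# Shared fixtures: small MCMC settings for unit tests and random-config
# generators for property-style checks. The reference (paper-scale) settings
# are exercised in test-acceptance.R only.

quick_mcmc <- function(seed = 1, n_chains = 2, n_draws = 600, n_burn_in = 300) {
  mcmc_config(n_chains = n_chains, n_draws = n_draws,
              n_burn_in = n_burn_in, seed = seed)
}

default_params <- function(...) mediation_params(...)

small_cohort <- function(n = 40, seed = 3, ...) {
  cohort_config(n_subjects = n, seed = seed, ...)
}

# Random but valid cohort configuration for round-trip property tests.
random_cohort_config <- function(seed) {
  set.seed(seed)
  params <- mediation_params(
    a = runif(1, -1, 1), b = runif(1, -1, 1),
    c_prime = runif(1, -1, 1), d = runif(1, -0.5, 0.5),
    i_m = runif(1, 0, 4), i_y = runif(1, 0, 4),
    sigma_m = runif(1, 0.1, 1.5), sigma_y = runif(1, 0.1, 1.5))
  cohort_config(n_subjects = sample(4:9, 1), params = params,
                z_mean = runif(1, 2, 8), z_sd = runif(1, 0.5, 3),
                fatigue_threshold = runif(1, 1, 6),
                render_precision = sample(1:3, 1),
                seed = sample.int(1e6, 1))
}

# A fabricated draws data.frame with equal-length chains, for summary tests.
fake_draws <- function(values_by_chain) {
  do.call(rbind, lapply(seq_along(values_by_chain), function(ch) {
    v <- values_by_chain[[ch]]
    data.frame(chain = ch, iteration = seq_along(v), a = v, b = v,
               cprime = v)
  }))
}
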
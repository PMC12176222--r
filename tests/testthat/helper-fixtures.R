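# Shared fixtures: small synthetic scenarios and one cached small fit so the
# expensive MCMC machinery is exercised once and reused across test files.

# Tiny scenario: quick to simulate, big enough to have all three streams.
tiny_scenario <- function(seed = 1L, n_years = 6L, n_units = 2L,
                          target_unit_harvest = 4000, ...) {
  ipm_scenario(n_years = n_years, n_units = n_units,
               target_unit_harvest = target_unit_harvest, seed = seed, ...)
}

fast_control <- function(seed = 1L, n_iterations = 1500L, n_burnin = 500L,
                         thin = 1L, n_adapt = 300L,
                         max_iterations = n_iterations) {
  mcmc_control(n_chains = 2L, n_iterations = n_iterations,
               n_burnin = n_burnin, thin = thin, n_adapt = n_adapt,
               max_iterations = max_iterations, seed = seed)
}

# One small fitted model, built on first use and cached for the session.
.fixture_env <- new.env(parent = emptyenv())
small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sim <- simulate_ipm(tiny_scenario(seed = 11L))
    .fixture_env$sim <- sim
    .fixture_env$fit <- ipm_fit(sim$data, control = fast_control(seed = 11L))
  }
  .fixture_env$fit
}
small_sim <- function() {
  small_fit()
  .fixture_env$sim
}
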
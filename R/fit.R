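# MCMC driver: chain configuration, the extend-until-converged protocol,
# and the fitted-model object.

#' MCMC configuration
#'
#' @param n_chains Number of chains (>= 2).
#' @param n_iterations Post-burn-in sampling iterations per batch and chain
#'   (before thinning).
#' @param n_burnin Burn-in iterations per chain.
#' @param thin Thinning interval (>= 1).
#' @param max_iterations Ceiling on total post-burn-in iterations per chain:
#'   if convergence is not reached after a batch, further batches of
#'   `n_iterations` are drawn (earlier batches then count as burn-in) until
#'   this ceiling.
#' @param n_adapt JAGS adaptation iterations.
#' @param seed Integer seed; all chain RNGs derive from it.
#' @param rhat_threshold Gelman-Rubin convergence threshold (default 1.1).
#' @return A list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_chains = 4L, n_iterations = 10000L,
                         n_burnin = 2000L, thin = 5L,
                         max_iterations = 30000L, n_adapt = 1000L,
                         seed = 1L, rhat_threshold = 1.1) {
  stopifnot(n_chains >= 2L, n_iterations >= 1L, n_burnin >= 0L, thin >= 1L,
            max_iterations >= n_iterations, n_adapt >= 0L)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 max_iterations = as.integer(max_iterations),
                 n_adapt = as.integer(n_adapt), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold),
            class = "mcmc_control")
}

#' Named MCMC profiles
#'
#' `"default"` is the desk-scale configuration (4 chains, 2,000 retained
#' draws each). `"full"` reproduces the heavy production protocol of large
#' statewide fits: 3 chains, 400,000-iteration batches, 500,000 burn-in,
#' thinning 50, extended until convergence or 5,500,000 iterations.
#'
#' @param profile `"default"` or `"full"`.
#' @param seed Integer seed.
#' @return An [mcmc_control()].
#' @export
mcmc_profile <- function(profile = c("default", "full"), seed = 1L) {
  profile <- match.arg(profile)
  switch(profile,
    default = mcmc_control(seed = seed),
    full = mcmc_control(n_chains = 3L, n_iterations = 400000L,
                        n_burnin = 500000L, thin = 50L,
                        max_iterations = 5500000L, seed = seed))
}

#' Run MCMC on an assembled joint model
#'
#' Compiles the model in JAGS, adapts, burns in, then draws batches of
#' `n_iterations` (thinned) until every monitored node's Gelman-Rubin
#' statistic is below `rhat_threshold` or `max_iterations` is reached; when
#' a run is extended, the retained draws are the most recent batch and the
#' earlier ones count as additional burn-in. Identical seed and
#' configuration give identical draws.
#'
#' @param model An [build_joint_model()] object.
#' @param control An [mcmc_control()].
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return An object of class `"harvest_ipm"` (see [ipm_fit()]).
#' @export
run_mcmc <- function(model, control = mcmc_control(), quiet = TRUE) {
  stopifnot(inherits(model, "ipm_model"), inherits(control, "mcmc_control"))
  inits <- lapply(seq_len(control$n_chains), model$inits, seed = control$seed)
  jm <- tryCatch(
    rjags::jags.model(textConnection(model$code), data = model$data,
                      inits = inits, n.chains = control$n_chains,
                      n.adapt = control$n_adapt, quiet = quiet),
    error = function(e)
      stop("JAGS model compilation/initialization failed: ",
           conditionMessage(e), call. = FALSE))
  if (control$n_burnin > 0L)
    stats::update(jm, control$n_burnin, progress.bar = "none")
  total <- 0L
  repeat {
    samples <- rjags::coda.samples(jm, model$monitors,
                                   n.iter = control$n_iterations,
                                   thin = control$thin,
                                   progress.bar = "none")
    total <- total + control$n_iterations
    rhat <- rhat_all(samples)
    converged <- all(rhat < control$rhat_threshold, na.rm = TRUE)
    if (converged || total + control$n_iterations > control$max_iterations)
      break
  }
  structure(list(samples = samples, rhat = rhat, converged = converged,
                 total_iterations = total, control = control, model = model,
                 dataset = model$dataset, priors = model$priors,
                 idx = model$idx),
            class = "harvest_ipm")
}

#' Fit the integrated population model to harvest data
#'
#' The package's main entry point: assembles the joint Bayesian model for a
#' harvest dataset (two-sex three-stage process model, hazard-scale rate
#' submodels with informative priors, the reported-harvest / age-at-harvest
#' / auxiliary-estimate observation streams) and samples its posterior with
#' MCMC.
#'
#' @param data A [harvest_data()] object (or the `$data` element of
#'   [simulate_ipm()]).
#' @param priors An [default_priors()] prior set.
#' @param control An [mcmc_control()] or [mcmc_profile()].
#' @param statewide_likelihood,aux_stream,init_abundance_override Passed to
#'   [build_joint_model()].
#' @param quiet Suppress sampler progress output.
#' @return An object of class `"harvest_ipm"` with components `samples`
#'   (a [coda::mcmc.list] of posterior draws for hyperparameters, latent
#'   abundance `N`, and harvest states `H`/`Hrep`), `rhat`, `converged`,
#'   `total_iterations`, and the inputs. Methods: `print`, `summary`,
#'   `coef`, `plot`, `simulate`, `fitted`, `residuals`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_ipm(ipm_scenario(n_years = 6, n_units = 1, seed = 7))
#' fit <- ipm_fit(sim$data,
#'                control = mcmc_control(n_iterations = 1000, thin = 1))
#' summary(fit)
#' }
ipm_fit <- function(data, priors = default_priors(),
                    control = mcmc_control(), statewide_likelihood = TRUE,
                    aux_stream = TRUE, init_abundance_override = NULL,
                    quiet = TRUE) {
  model <- build_joint_model(data, priors,
                             statewide_likelihood = statewide_likelihood,
                             aux_stream = aux_stream,
                             init_abundance_override = init_abundance_override)
  run_mcmc(model, control, quiet = quiet)
}
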
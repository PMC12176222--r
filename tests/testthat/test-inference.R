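# Convergence machinery, posterior summaries, and the MCMC driver's
# contracts (determinism, extension protocol, structure of the fit).

test_that("Gelman-Rubin reproduces hand-evaluated values", {
  # two identical chains [1,2,3]: B = 0, W = 1, n = 3 -> sqrt(2/3)
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(1, 2, 3))), sqrt(2 / 3))
  # zero within-chain variance everywhere is defined as 1
  expect_equal(gelman_rubin(list(c(2, 2, 2), c(2, 2, 2))), 1)
  # chains from the same distribution are near 1
  set.seed(7)
  ch <- replicate(4, rnorm(10000), simplify = FALSE)
  expect_gt(gelman_rubin(ch), 0.99)
  expect_lt(gelman_rubin(ch), 1.01)
  # well-separated chains blow far past the threshold
  expect_gt(gelman_rubin(list(rnorm(500, 0), rnorm(500, 10))), 1.1)
  expect_error(gelman_rubin(list(1:3)), "2 chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal length")
})

test_that("split Rhat flags within-chain drift that the classic form misses", {
  trend <- seq(0, 3, length.out = 1000)
  set.seed(8)
  drifting <- lapply(1:3, function(i) trend + rnorm(1000, 0, 0.1))
  expect_lt(gelman_rubin(drifting), 1.1) # chains agree with each other
  expect_gt(split_rhat(drifting), 1.1)   # but each chain is still moving
  # and split Rhat agrees with the classic one on stationary chains
  set.seed(9)
  stat <- lapply(1:3, function(i) rnorm(1000))
  expect_equal(split_rhat(stat), gelman_rubin(stat), tolerance = 0.01)
})

test_that("posterior summaries use median, equal-tailed 90% CRI and CV", {
  s <- summarize_draws(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$lower90, unname(quantile(1:100, 0.05, type = 7)))
  expect_equal(s$upper90, unname(quantile(1:100, 0.95, type = 7)))
  sc <- summarize_draws(rep(3, 10))
  expect_equal(c(sc$lower90, sc$median, sc$upper90), c(3, 3, 3))
  expect_equal(sc$cv, 0)
  set.seed(10)
  x <- rnorm(1e5, 100, 10)
  expect_equal(summarize_draws(x)$cv, 10, tolerance = 0.02)
  # CV is undefined (missing) for a quantity with nonpositive mean
  expect_true(is.na(summarize_draws(rnorm(100, 0, 1e-9) - 1)$cv))
  expect_error(summarize_draws(1), "2 draws")
})

test_that("growth rates telescope to the geometric mean", {
  g <- growth_rates(c(100, 110))
  expect_equal(g$lambda, 1.1)
  expect_equal(g$geometric_mean, 1.1)
  g2 <- growth_rates(c(100, 110, 121))
  expect_equal(g2$geometric_mean, 1.1)
  expect_equal(g2$geometric_mean, prod(g2$lambda)^(1 / 2))
  # a trajectory returning to its start has geometric mean exactly 1
  g3 <- growth_rates(c(50, 80, 30, 50))
  expect_equal(g3$geometric_mean, 1)
  # identity holds to machine precision on arbitrary positive series
  set.seed(11)
  for (r in 1:20) {
    N <- exp(cumsum(rnorm(8, 0, 0.2))) * 1000
    g <- growth_rates(N)
    expect_equal(prod(g$lambda)^(1 / (length(N) - 1)),
                 (N[length(N)] / N[1])^(1 / (length(N) - 1)))
  }
  expect_error(growth_rates(c(10, 0, 5)), "positive")
})

test_that("population density scales as expected", {
  expect_equal(population_density(890657, 109150), 8.16, tolerance = 1e-3)
  expect_equal(round(population_density(890657, 109150)), 8)
  expect_equal(population_density(0, 50), 0)
  expect_equal(population_density(100, 50), 2 * population_density(100, 100))
  expect_error(population_density(10, 0), "positive")
})

test_that("class proportions partition the population", {
  # three hand-made draws
  N <- array(0, c(3, 3, 2))
  N[1, , ] <- matrix(rep(100, 6), 3, 2)            # equal classes
  N[2, , ] <- matrix(c(10, 20, 30, 40, 50, 60), 3, 2)
  N[3, , ] <- matrix(c(0, 0, 210, 0, 0, 0), 3, 2)  # all adult females
  p <- class_proportions(N, groups = list(
    females = c("yearling.F", "adult.F"),
    males = c("yearling.M", "adult.M"),
    fawns = c("fawn.F", "fawn.M")))
  expect_equal(unname(p[1, ]), c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(unname(p[2, ]), c(50 / 210, 110 / 210, 50 / 210))
  expect_equal(unname(p[3, ]), c(1, 0, 0))
  # an exhaustive partition sums to one
  expect_equal(unname(rowSums(p)), rep(1, 3))
  expect_error(class_proportions(N, groups = list(x = "calf.F")), "unknown")
})

test_that("the MCMC driver is deterministic and respects its iteration ceiling", {
  sim <- simulate_ipm(tiny_scenario(seed = 61, n_years = 4, n_units = 1,
                                    target_unit_harvest = 2000))
  ctl <- fast_control(seed = 3, n_iterations = 400L, n_burnin = 200L,
                      n_adapt = 200L)
  f1 <- ipm_fit(sim$data, control = ctl)
  f2 <- ipm_fit(sim$data, control = ctl)
  expect_equal(summary(f1), summary(f2))
  expect_identical(lapply(f1$samples, as.matrix),
                   lapply(f2$samples, as.matrix))
  # a deliberately short run on this target does not converge, and the
  # extension protocol stops at max_iterations
  expect_false(f1$converged)
  expect_equal(f1$total_iterations, 400L)
  ctl2 <- fast_control(seed = 3, n_iterations = 150L, n_burnin = 100L,
                       n_adapt = 200L, max_iterations = 300L)
  f3 <- ipm_fit(sim$data, control = ctl2)
  expect_false(f3$converged)
  expect_equal(f3$total_iterations, 300L)
  expect_lte(f3$total_iterations, ctl2$max_iterations)
})

test_that("the assembled joint model is well-posed and validates its inputs", {
  sim <- small_sim()
  model <- build_joint_model(sim$data)
  expect_s3_class(model, "ipm_model")
  expect_true(all(c("mu.NS", "N", "Hrep") %in% model$monitors))
  # the observed-data log-likelihood is finite at the generating state
  ll <- ipm_loglik(sim$data, sim$truth$N + 0.5, sim$truth$HS, sim$truth$R,
                   sigma_Hest = 0.1 * mean(sim$data$y_Hest, na.rm = TRUE))
  expect_true(is.finite(ll))
  # missing stream -> structural error
  broken <- sim$data
  broken$y_A <- NULL
  expect_error(build_joint_model(broken), "age")
})

test_that("a fitted model exposes draws, Rhat and abundance trajectories", {
  fit <- small_fit()
  expect_s3_class(fit, "harvest_ipm")
  expect_equal(length(fit$samples), 2L)
  expect_true(all(is.finite(fit$rhat)))
  # deterministic reference offsets have Rhat defined as 1
  expect_equal(unname(fit$rhat["lhr.NS[3]"]), 1)
  Nt <- total_abundance(fit)
  expect_equal(dim(Nt), c(2L * 1500L, 6L))
  expect_true(all(Nt > 0))
  # unit-level trajectories sum to the statewide one
  Nu <- total_abundance(fit, "unit")
  expect_equal(Nu[, , 1] + Nu[, , 2], Nt)
  gs <- growth_summary(fit)
  expect_equal(nrow(gs$lambda), 5L)
  expect_true(gs$geometric_mean$median > 0.8 && gs$geometric_mean$median < 1.2)
})
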
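# The exact-simulation generator: deterministic limits, binomial oracles,
# determinism, and the structure of the observed data streams.

# Rates with essentially no mortality/harvest/reporting loss and (near-)zero
# recruitment: the projection becomes a deterministic shift.
deterministic_rates <- function() {
  ipm_true_rates(mu_NS = c(-30, -30), mu_HS = c(-30, -30), mu_R = c(-2, -2),
                 mu_rec = -30, sigma_NS = 0, sigma_HS = 0, sigma_R = 0,
                 sigma_rec = 0)
}

test_that("with survival one and no recruitment the stages shift deterministically", {
  init <- array(0L, c(3, 2, 1))
  init[, , 1] <- matrix(c(500, 300, 800, 450, 250, 700), 3, 2)
  cfg <- ipm_scenario(n_years = 5, n_units = 1, initial_abundance = init,
                      true_rates = deterministic_rates(), seed = 3)
  truth <- simulate_population(cfg)
  for (t in 1:4) for (s in 1:2) {
    expect_equal(truth$N[2, t + 1, s, 1], truth$N[1, t, s, 1])
    expect_equal(truth$N[3, t + 1, s, 1],
                 truth$N[2, t, s, 1] + truth$N[3, t, s, 1])
  }
  # fawn cohorts die out after year 1 and nothing is harvested
  expect_equal(truth$N[1, 2:5, , 1], array(0L, c(4, 2)))
  expect_true(all(truth$H == 0))
  # yearling + adult abundance is conserved once the fawns have promoted
  totals <- apply(truth$N[2:3, , , 1], 2, sum)
  expect_equal(totals[1], sum(init[2:3, , 1]))
  expect_equal(totals[2:5], rep(sum(init), 4))
})

test_that("yearling transition matches the binomial mean oracle", {
  # N_fawn = 1000 with HS * NS = 0.81: mean next-year yearlings is np = 810
  p_each <- sqrt(0.81) # HS = NS = 0.9
  mu <- cloglog_link(p_each)
  tr <- ipm_true_rates(mu_NS = c(mu, mu), mu_HS = c(mu, mu),
                       mu_rec = -30, sigma_NS = 0, sigma_HS = 0,
                       sigma_R = 0, sigma_rec = 0)
  init <- array(0L, c(3, 2, 1)); init[1, 1, 1] <- 1000L
  n_rep <- 3000
  draws <- vapply(seq_len(n_rep), function(r) {
    cfg <- ipm_scenario(n_years = 3, n_units = 1, initial_abundance = init,
                        true_rates = tr, seed = r)
    simulate_population(cfg)$N[2, 2, 1, 1]
  }, numeric(1))
  se <- sqrt(1000 * 0.81 * 0.19 / n_rep)
  expect_lt(abs(mean(draws) - 810), 3 * se)
})

test_that("identical seeds reproduce the simulation bitwise", {
  cfg <- ipm_scenario(n_years = 6, n_units = 2, seed = 99,
                      target_unit_harvest = 3000)
  s1 <- simulate_ipm(cfg)
  s2 <- simulate_ipm(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$data, s2$data)
  # a different seed gives different realizations
  cfg2 <- ipm_scenario(n_years = 6, n_units = 2, seed = 100,
                       target_unit_harvest = 3000)
  expect_false(identical(simulate_population(cfg2)$N, s1$truth$N))
})

test_that("realized harvest respects ordering and reacts to hunting survival", {
  sim <- simulate_ipm(tiny_scenario(seed = 5))
  expect_true(all(sim$truth$Hrep <= sim$truth$H))
  expect_true(all(sim$truth$H <= sim$truth$N))
  expect_true(all(sim$truth$N >= 0))
  # higher hunting survival lowers realized harvest
  hi <- tiny_scenario(seed = 5, true_rates = ipm_true_rates(mu_HS = c(-2.6, -2.2)))
  hi$initial_abundance <- sim$truth$config$initial_abundance
  expect_lt(sum(simulate_population(hi)$H[, 1, , ]),
            sum(sim$truth$H[, 1, , ]))
})

test_that("observed streams aggregate the reported harvest correctly", {
  sim <- simulate_ipm(tiny_scenario(seed = 7))
  truth <- sim$truth; d <- sim$data
  for (t in c(1, 4)) for (i in 1:2) {
    expect_equal(d$y_H[t, "Antlerless", i],
                 sum(truth$Hrep[, t, 1, i]) + truth$Hrep[1, t, 2, i])
    expect_equal(d$y_H[t, "Antlered", i],
                 truth$Hrep[2, t, 2, i] + truth$Hrep[3, t, 2, i])
  }
  # the two bags partition the reported harvest
  expect_equal(sum(d$y_H), sum(truth$Hrep))
  # auxiliary estimates exist exactly for the declared years
  expect_equal(which(!is.na(d$y_Hest[, 1])), d$aux_years)
  # realized aged-sexed fraction is near its target
  frac <- sum(d$y_A) / sum(d$y_H)
  n <- sum(d$y_H)
  expect_lt(abs(frac - 0.03), 4 * sqrt(0.03 * 0.97 / n))
})

test_that("subsampling and auxiliary noise vanish in their limits", {
  cfg <- tiny_scenario(seed = 13, aged_sexed_fraction = 1 - 1e-12,
                       aux_cv = 1e-12)
  sim <- simulate_ipm(cfg)
  # aged-sexed counts equal the reported harvest per class
  expect_equal(unname(c(sim$data$y_A)), c(sim$truth$Hrep))
  # auxiliary estimates equal the true total harvest by bag
  swH <- apply(sim$truth$H, 1:3, sum)
  for (t in cfg$aux_years) {
    expect_equal(unname(sim$data$y_Hest[t, ]),
                 unname(bag_expectations(swH[, t, ])), tolerance = 1e-6)
  }
})

test_that("invalid configurations are rejected with informative messages", {
  expect_error(ipm_scenario(n_years = 2), "n_years")
  expect_error(ipm_scenario(aged_sexed_fraction = 0), "aged_sexed_fraction")
  expect_error(ipm_scenario(aux_years = 25), "aux_years")
  expect_error(ipm_true_rates(mu_HS = c(NaN, -1)), "mu_HS")
  expect_error(ipm_true_rates(lhr_NS = c(0, 0, 1)), "lhr_NS")
  expect_error(ipm_true_rates(sigma_R = -0.1), "sigma_R")
})
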
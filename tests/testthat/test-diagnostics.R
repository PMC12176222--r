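# Prior evaluation and goodness-of-fit diagnostics.

test_that("prior-posterior overlap matches closed forms for normal pairs", {
  set.seed(101)
  # equal-variance normals two and a half SDs apart: overlap = 2*pnorm(-1.25... )
  draws <- rnorm(1e5, 5, 1)
  ov <- prior_posterior_overlap(draws, normal_dist(0, 1))
  expect_equal(ov, 2 * pnorm(-2.5), tolerance = 0.01)
  # sampling from the prior itself gives near-total overlap
  ov_self <- prior_posterior_overlap(rnorm(1e5, 0, 1), normal_dist(0, 1))
  expect_gte(ov_self, 0.95)
  expect_lte(ov_self, 1)
  # disjoint supports: posterior mass far outside a tight prior
  ov0 <- prior_posterior_overlap(runif(1000, 100, 101), normal_dist(0, 0.1))
  expect_lt(ov0, 1e-6)
  expect_error(prior_posterior_overlap(rnorm(50), normal_dist(0, 1)), "100")
  expect_warning(ovd <- prior_posterior_overlap(rep(1, 200), normal_dist(0, 1)),
                 "degenerate")
  expect_equal(ovd, 0)
})

test_that("data-agreement criterion matches the closed-form normal KL ratio", {
  # post N(0,1), prior N(1,1), benchmark N(0,2):
  # KL(post||prior) = 1/2; KL(post||bench) = log 2 + 1/8 - 1/2
  kl1 <- 0.5
  kl2 <- log(2) + 1 / 8 - 1 / 2
  set.seed(102)
  draws <- rnorm(1e5)
  dac <- data_agreement_criterion(draws, normal_dist(1, 1), normal_dist(0, 2))
  expect_equal(dac, kl1 / kl2, tolerance = 0.01)
  expect_equal(kl1 / kl2, 1.572, tolerance = 1e-3)
  # widening the prior SD by 25% strictly decreases the criterion
  dac_w <- data_agreement_criterion(draws, normal_dist(1, 1.25),
                                    normal_dist(0, 2))
  expect_lt(dac_w, dac)
  kl1_w <- log(1.25) + (1 + 1) / (2 * 1.25^2) - 1 / 2
  expect_equal(dac_w, kl1_w / kl2, tolerance = 0.02)
  # posterior identical to the prior: numerator vanishes
  dac0 <- data_agreement_criterion(draws, normal_dist(0, 1), normal_dist(0, 2))
  expect_lt(dac0, 0.05)
  # monotone decrease over successive 25% widenings (the closed form
  # 0.500, 0.363, 0.356 over SDs 1, 1.25, 1.5625; far beyond that the
  # divergence eventually grows again as the prior becomes too diffuse)
  dacs <- vapply(c(1, 1.25, 1.5625), function(f)
    data_agreement_criterion(draws, normal_dist(1, f), normal_dist(0, 4)),
    numeric(1))
  expect_true(all(diff(dacs) < 0))
})

test_that("overlap is symmetric between comparable densities", {
  set.seed(103)
  a <- rnorm(5e4, 0, 1)
  b <- rnorm(5e4, 1.5, 1)
  ov_ab <- prior_posterior_overlap(a, normal_dist(1.5, 1))
  ov_ba <- prior_posterior_overlap(b, normal_dist(0, 1))
  expect_equal(ov_ab, ov_ba, tolerance = 0.02)
  expect_true(ov_ab >= 0 && ov_ab <= 1)
})

test_that("discrepancy statistics match hand arithmetic", {
  expect_equal(chi_squared_discrepancy(c(10, 20), c(20, 10)), 15)
  expect_equal(chi_squared_discrepancy(c(5, 5), c(5, 5)), 0)
  expect_equal(chi_squared_discrepancy(c(10, 20, 7), c(20, 10, 7)),
               chi_squared_discrepancy(c(7, 20, 10), c(7, 10, 20)))
  expect_equal(freeman_tukey_discrepancy(c(1, 4), c(4, 1)), 2)
  expect_equal(freeman_tukey_discrepancy(c(3, 3), c(3, 3)), 0)
  # adding a perfectly fitting cell changes nothing
  expect_equal(freeman_tukey_discrepancy(c(1, 4, 9), c(4, 1, 9)), 2)
  expect_error(freeman_tukey_discrepancy(c(-1, 1), c(1, 1)), "nonnegative")
})

test_that("posterior predictive checks behave sensibly on a self-consistent fit", {
  fit <- small_fit()
  streams <- c("harvest_totals", "age_female", "age_male", "aux_estimates")
  for (s in streams) {
    ppc <- posterior_predictive_check(fit, s, n_draws = 200, seed = 4)
    expect_s3_class(ppc, "ipm_ppc")
    expect_equal(ppc$bayesian_p, mean(ppc$T_rep > ppc$T_obs))
    expect_true(ppc$bayesian_p >= 0 && ppc$bayesian_p <= 1)
    expect_equal(length(ppc$T_obs), length(ppc$T_rep))
  }
  # default statistic mapping follows the stream
  expect_equal(posterior_predictive_check(fit, "harvest_totals",
                                          n_draws = 20)$statistic,
               "chi_squared")
  expect_equal(posterior_predictive_check(fit, "age_male",
                                          n_draws = 20)$statistic,
               "freeman_tukey")
  # grossly inflated observations are detected as extreme misfit: the
  # observed discrepancy dwarfs every replicate's, so the strict
  # mean(T_rep > T_obs) p-value collapses to 0
  inflated <- fit
  inflated$dataset$y_H <- fit$dataset$y_H * 10
  p_inf <- posterior_predictive_check(inflated, "harvest_totals",
                                      n_draws = 100, seed = 4)$bayesian_p
  expect_lte(p_inf, 0.01)
})

test_that("prior evaluation applies the overlap threshold and widening rule", {
  fit <- small_fit()
  pe <- evaluate_priors(fit)
  expect_s3_class(pe, "ipm_prior_eval")
  expect_true(all(pe$overlap >= 0 & pe$overlap <= 1))
  # DAC is computed exactly when overlap exceeds the threshold
  expect_equal(is.na(pe$dac), pe$overlap <= 0.35)
  # widening is flagged exactly when DAC > 1
  expect_equal(pe$widened, !is.na(pe$dac) & pe$dac > 1)
  wp <- attr(pe, "widened_priors")
  expect_s3_class(wp, "ipm_priors")
  for (k in seq_len(nrow(pe))) {
    if (!pe$widened[k]) next
    par <- pe$parameter[k]
    if (grepl("^mu\\.(NS|HS|R)\\[", par)) {
      rate <- sub("^mu\\.", "", sub("\\[.*", "", par))
      j <- as.integer(sub(".*\\[(\\d)\\]", "\\1", par))
      expect_equal(wp[[rate]]$sd[[j]], fit$priors[[rate]]$sd[[j]] * 1.25)
    }
  }
  # a higher threshold suppresses DAC computation entirely
  pe2 <- evaluate_priors(fit, threshold = 1)
  expect_true(all(is.na(pe2$dac)))
  expect_false(any(pe2$widened))
})
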
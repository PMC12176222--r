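# Link functions, rate assembly, and moment-matched projections.

test_that("survival link inverts log cumulative hazard and saturates", {
  expect_equal(survival_from_linpred(-2.12), exp(-exp(-2.12)))
  expect_equal(survival_from_linpred(-2.12), 0.8869, tolerance = 1e-4)
  expect_equal(survival_from_linpred(0), exp(-1))
  expect_equal(survival_from_linpred(-Inf), 1)
  expect_equal(survival_from_linpred(Inf), 0)
  # strictly decreasing, maps onto (0, 1)
  eta <- seq(-8, 4, length.out = 200)
  s <- survival_from_linpred(eta)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s < 1))
  # round trip with the forward link
  p <- c(0.01, 0.3679, 0.8868, 0.999)
  expect_equal(survival_from_linpred(cloglog_link(p)), p)
})

test_that("hazard-ratio offsets act multiplicatively on the hazard", {
  eta <- -1.2
  # adding log(k) raises survival to the k-th power
  for (k in c(0.5, 2, 3)) {
    expect_equal(survival_from_linpred(eta + log(k)),
                 survival_from_linpred(eta)^k)
  }
})

test_that("assemble_rate builds the linear predictor elementwise", {
  idx <- ipm_index(4, 2)
  eps <- matrix(0, 4, 2)
  r <- assemble_rate(c(-1.8, -0.96), c(0, 0, 0), eps, idx)
  expect_equal(dim(r), c(3L, 4L, 2L, 2L))
  expect_equal(r[1, 1, 1, 1], 0.8477, tolerance = 1e-4)
  expect_equal(unique(c(r[, , 2, ])), survival_from_linpred(-0.96))
  # age offset log(2) squares the reference-age survival
  r2 <- assemble_rate(c(-1.8, -0.96), c(log(2), 0, 0), eps, idx)
  expect_equal(r2[1, , , ], r[1, , , ]^2)
  # random effect enters per year/unit
  eps[2, 1] <- 0.5
  r3 <- assemble_rate(c(-1.8, -0.96), c(0, 0, 0), eps, idx)
  expect_equal(r3[1, 2, 1, 1], survival_from_linpred(-1.8 + 0.5))
  expect_equal(r3[1, 2, 1, 2], survival_from_linpred(-1.8))
  # log link: recruitment with zero fawn class
  g <- assemble_rate(-0.35, eps = array(0, c(2, 4, 2)), idx = idx, link = "log")
  expect_equal(dim(g), c(3L, 4L, 2L))
  expect_equal(g[1, , ], array(0, c(4, 2)))
  expect_equal(g[2, 1, 1], 0.7047, tolerance = 1e-4)
  # dimension mismatches name the axis
  expect_error(assemble_rate(c(-1.8, -0.96), c(0, 0, 0), matrix(0, 3, 2), idx),
               "year")
  expect_error(assemble_rate(-1.8, c(0, 0, 0), eps, idx), "sex")
})

test_that("moment matching reproduces exact binomial and Poisson moments", {
  mm <- moment_matched_binomial(1000, 0.81)
  expect_equal(mm$mean, 810)
  expect_equal(mm$variance, 153.9)
  # degenerate cases hit the variance floor
  expect_equal(moment_matched_binomial(50, 1), list(mean = 50, variance = 1e-6))
  expect_equal(moment_matched_binomial(0, 0.3), list(mean = 0, variance = 1e-6))
  expect_error(moment_matched_binomial(-1, 0.5), "nonnegative")
  expect_error(moment_matched_binomial(10, 1.2))
  mp <- moment_matched_poisson(50.34)
  expect_equal(mp$mean, 50.34)
  expect_equal(mp$variance, 50.34)
  expect_equal(moment_matched_poisson(0)$variance, 1e-6)
  expect_error(moment_matched_poisson(-2), "nonnegative")
  # Monte-Carlo agreement with the exact Poisson at lambda = 20
  set.seed(1)
  x <- rpois(2e5, 20)
  expect_equal(mean(x), moment_matched_poisson(20)$mean, tolerance = 0.01)
  expect_equal(var(x), moment_matched_poisson(20)$variance, tolerance = 0.02)
})

test_that("stage projections compose binomial moments", {
  y <- project_yearlings(1000, 0.9, 0.9)
  expect_equal(y$mean, 810)
  expect_equal(y$variance, 153.9)
  expect_equal(project_yearlings(500, 1, 1)$mean, 500)
  expect_equal(project_yearlings(0, 0.5, 0.5)$mean, 0)
  a <- project_adults(500, 1000, 0.9, 0.9, 0.8, 0.8)
  expect_equal(a$mean, 500 * 0.81 + 1000 * 0.64)
  expect_equal(a$variance, 500 * 0.81 * 0.19 + 1000 * 0.64 * 0.36)
  expect_equal(a$mean, 1045)
  expect_equal(a$variance, 76.95 + 230.4)
  expect_equal(project_adults(500, 1000, 1, 1, 1, 1)$mean, 1500)
  expect_equal(project_adults(0, 0, 0.9, 0.9, 0.8, 0.8)$mean, 0)
})

test_that("fawn intensity follows the eight-month survival formulation", {
  expect_equal(fawn_intensity(100, 0.9, 0.9, 1.2, 0.5),
               100 * 0.9^(2 / 3) * 0.9 * 1.2 * 0.5)
  expect_equal(fawn_intensity(100, 0.9, 0.9, 1.2, 0.5), 50.34, tolerance = 1e-3)
  expect_equal(fawn_intensity(c(100, 200), c(0.9, 0.8), c(0.9, 0.7),
                              c(0, 0), 0.5), 0)
  # an even sex ratio splits the intensity equally
  lam <- function(s) fawn_intensity(c(10, 50, 70), c(0.7, 0.95, 0.9),
                                    c(0.95, 0.9, 0.85), c(0, 1.1, 1.3), s)
  expect_equal(lam(0.5) * 2, lam(1))
})

test_that("deterministic mean projection conserves animals", {
  idx <- ipm_index(5, 1)
  NS <- assemble_rate(c(-2.12, -1.6), c(0, 0, 0), matrix(0, 5, 1), idx)
  HS <- assemble_rate(c(-1.8, -0.96), c(0, 0, 0), matrix(0, 5, 1), idx)
  gam <- assemble_rate(-0.35, eps = array(0, c(2, 5, 1)), idx = idx,
                       link = "log")
  N1 <- matrix(c(400, 300, 900, 380, 280, 700), 3, 2)
  N <- project_mean(N1, NS, HS, gam, idx)
  # every transition equals survivors plus recruits computed directly
  for (t in 1:4) for (s in 1:2) {
    expect_equal(N[2, t + 1, s, 1], N[1, t, s, 1] * HS[1, t, s, 1] * NS[1, t, s, 1])
    expect_equal(N[3, t + 1, s, 1],
                 N[2, t, s, 1] * HS[2, t, s, 1] * NS[2, t, s, 1] +
                 N[3, t, s, 1] * HS[3, t, s, 1] * NS[3, t, s, 1])
    expect_equal(N[1, t + 1, s, 1],
                 fawn_intensity(N[, t, 1, 1], NS[, t, 1, 1], HS[, t, 1, 1],
                                gam[, t, 1], 0.5))
  }
  # with survival 1 and no recruitment, yearlings + adults are conserved
  one <- array(1, c(3, 5, 2, 1))
  zero <- array(0, c(3, 5, 1))
  Nc <- project_mean(N1, one, one, zero, idx)
  totals <- apply(Nc[2:3, , , , drop = FALSE], 2, sum)
  expect_equal(totals[1], sum(N1[2:3, ]))
  expect_equal(totals[2:5], rep(sum(N1), 4))
})

test_that("stable stage distribution is a fixed point of the projection", {
  NS <- matrix(c(0.89, 0.98, 0.81, 0.82, 0.98, 0.93), 3, 2)
  HS <- matrix(c(0.94, 0.85, 0.85, 0.94, 0.7, 0.74), 3, 2)
  gam <- c(0, 1.1, 1.2)
  ss <- stable_stage_distribution(NS, HS, gam)
  expect_equal(sum(ss$shares), 1)
  # one more projection step scales the structure by lambda
  n <- ss$shares
  nn <- matrix(0, 3, 2)
  for (s in 1:2) {
    nn[2, s] <- n[1, s] * HS[1, s] * NS[1, s]
    nn[3, s] <- n[2, s] * HS[2, s] * NS[2, s] + n[3, s] * HS[3, s] * NS[3, s]
    nn[1, s] <- fawn_intensity(n[, 1], NS[, 1], HS[, 1], gam, 0.5)
  }
  expect_equal(nn / sum(nn), n, tolerance = 1e-8)
  expect_equal(sum(nn) / sum(n), ss$lambda, tolerance = 1e-8)
})

test_that("moment-matched normal stays close to the exact binomial CDF", {
  # midpoint-evaluated Kolmogorov-Smirnov distance between the discrete
  # binomial and its continuous normal approximant
  ks_mid <- function(n, p) {
    k <- 0:n
    max(abs(pbinom(k, n, p) - pnorm(k + 0.5, n * p, sqrt(n * p * (1 - p)))))
  }
  for (n in c(100, 400, 2000)) for (p in c(0.1, 0.3, 0.5, 0.8, 0.95)) {
    expect_lt(ks_mid(n, p), 0.05)
  }
})
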
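# Synthetic-data generator: exact binomial/Poisson forward simulation of the
# population and harvest process. Deliberately avoids the inference model's
# normal approximations so it can serve as an independent oracle.

#' True-rate parameter list for a synthetic scenario
#'
#' @param mu_NS,mu_HS,mu_R Length-2 (F, M) link-scale baselines.
#' @param mu_rec Log-scale recruitment baseline.
#' @param lhr_NS,lhr_HS,lhr_R Length-3 age offsets (log hazard ratios;
#'   adult is the reference and must be 0).
#' @param sigma_NS,sigma_HS,sigma_R,sigma_rec Random-effect SDs (>= 0).
#' @return A named list of true rates on their link scales.
#' @export
ipm_true_rates <- function(mu_NS = c(-2.12, -1.60), mu_HS = c(-1.80, -0.96),
                           mu_R = c(-1.50, -1.30), mu_rec = -0.35,
                           lhr_NS = c(0, 0, 0), lhr_HS = c(0, 0, 0),
                           lhr_R = c(0, 0, 0),
                           sigma_NS = 0.07, sigma_HS = 0.14,
                           sigma_R = 0.10, sigma_rec = 0.16) {
  rates <- list(mu_NS = mu_NS, mu_HS = mu_HS, mu_R = mu_R, mu_rec = mu_rec,
                lhr_NS = lhr_NS, lhr_HS = lhr_HS, lhr_R = lhr_R,
                sigma_NS = sigma_NS, sigma_HS = sigma_HS,
                sigma_R = sigma_R, sigma_rec = sigma_rec)
  for (nm in c("mu_NS", "mu_HS", "mu_R"))
    if (length(rates[[nm]]) != 2L || any(!is.finite(rates[[nm]])))
      stop(nm, " must be two finite link-scale baselines (F, M)", call. = FALSE)
  for (nm in c("lhr_NS", "lhr_HS", "lhr_R")) {
    v <- rates[[nm]]
    if (length(v) != 3L || any(!is.finite(v)) || v[3L] != 0)
      stop(nm, " must be three finite offsets with the adult reference 0",
           call. = FALSE)
  }
  for (nm in c("sigma_NS", "sigma_HS", "sigma_R", "sigma_rec"))
    if (!is.finite(rates[[nm]]) || rates[[nm]] < 0)
      stop(nm, " must be a nonnegative finite SD", call. = FALSE)
  if (!is.finite(exp(rates$mu_rec)))
    stop("mu_rec implies a non-finite recruitment rate", call. = FALSE)
  rates
}

#' Synthetic-scenario configuration
#'
#' Defines the study conditions of a simulated harvest monitoring program.
#' The defaults emulate a statewide deer program: 19 harvest years, 6
#' management units, aged-and-sexed subsampling of 3% of the reported
#' harvest, auxiliary total-harvest estimates (CV 10%) in the final 5 years
#' only, true rates at the default prior means, and initial abundance sized
#' so a unit reports about 26,700 deer per year.
#'
#' @param n_years Number of years (>= 3).
#' @param n_units Number of units (>= 1).
#' @param initial_abundance `3 x 2 x I` array of nonnegative integers, or
#'   `NULL` to size it from `target_unit_harvest` at the stable
#'   stage-and-sex distribution of the true rates.
#' @param true_rates An [ipm_true_rates()] list.
#' @param aged_sexed_fraction Probability a reported kill is aged and sexed,
#'   in (0, 1).
#' @param aux_years Years with auxiliary estimates (default: final 5, or all
#'   years if fewer).
#' @param aux_cv Coefficient of variation of the auxiliary estimates (> 0).
#' @param target_unit_harvest Expected first-year reported harvest per unit,
#'   used only when `initial_abundance` is `NULL`.
#' @param unit_area Length-`I` unit areas in km^2 (default: a 109,150 km^2
#'   state split evenly).
#' @param seed Integer seed; identical seeds give identical simulations.
#' @return An object of class `"ipm_scenario"`.
#' @export
ipm_scenario <- function(n_years = 19L, n_units = 6L,
                         initial_abundance = NULL,
                         true_rates = ipm_true_rates(),
                         aged_sexed_fraction = 0.03,
                         aux_years = NULL, aux_cv = 0.10,
                         target_unit_harvest = 26674,
                         unit_area = NULL, seed = 1L) {
  idx <- ipm_index(n_years, n_units)
  if (!is.finite(aged_sexed_fraction) ||
      aged_sexed_fraction <= 0 || aged_sexed_fraction >= 1)
    stop("aged_sexed_fraction must lie in (0, 1)", call. = FALSE)
  if (!is.finite(aux_cv) || aux_cv < 0)
    stop("aux_cv must be nonnegative", call. = FALSE)
  if (is.null(aux_years)) aux_years <- seq_len(idx$T) |> utils::tail(5L)
  aux_years <- sort(unique(as.integer(aux_years)))
  if (length(aux_years) && (min(aux_years) < 1L || max(aux_years) > idx$T))
    stop("aux_years must be a subset of 1..n_years", call. = FALSE)
  if (is.null(unit_area)) unit_area <- rep(109150 / idx$I, idx$I)
  stopifnot(length(unit_area) == idx$I, all(unit_area > 0))

  rates0 <- scenario_mean_rates(true_rates)
  if (is.null(initial_abundance)) {
    ss <- stable_stage_distribution(rates0$NS, rates0$HS, rates0$gamma)
    frac <- sum(ss$shares * (1 - rates0$HS) * rates0$R)
    total <- target_unit_harvest / frac
    initial_abundance <- array(round(rep(total * ss$shares, idx$I)),
                               c(idx$A, idx$S, idx$I))
  } else {
    initial_abundance <- array(initial_abundance, c(idx$A, idx$S, idx$I))
    if (any(initial_abundance < 0) ||
        any(initial_abundance != round(initial_abundance)))
      stop("initial_abundance must be nonnegative integers", call. = FALSE)
  }
  structure(list(idx = idx, initial_abundance = initial_abundance,
                 true_rates = true_rates,
                 aged_sexed_fraction = aged_sexed_fraction,
                 aux_years = aux_years, aux_cv = aux_cv,
                 unit_area = unit_area, seed = as.integer(seed)),
            class = "ipm_scenario")
}

# A x S prior/true mean rate matrices from an ipm_true_rates list.
scenario_mean_rates <- function(tr) {
  m <- function(mu, lhr) {
    out <- matrix(NA_real_, 3L, 2L, dimnames = list(AGES, SEXES))
    for (s in 1:2) out[, s] <- survival_from_linpred(mu[s] + lhr)
    out
  }
  list(NS = m(tr$mu_NS, tr$lhr_NS), HS = m(tr$mu_HS, tr$lhr_HS),
       R = m(tr$mu_R, tr$lhr_R), gamma = c(0, rep(exp(tr$mu_rec), 2)))
}

#' Forward-simulate the true population and harvest
#'
#' Generates a ground-truth population by exact stochastic simulation of the
#' two-sex, three-stage post-birth-pulse process: random effects are drawn
#' on the link scales, survival transitions are exact binomials, fawn
#' production is exact Poisson, harvest is Binomial(N, 1 - HS) per class,
#' and reporting is Binomial(H, R). Harvested animals cannot also survive:
#' the annual survivors are drawn from the hunting-season survivors, and
#' mothers are hunting-season survivors thinned by `NS^(8/12)` (fall census
#' to the June birth pulse) before producing fawns at rate `gamma`, split
#' equally between the sexes at birth.
#'
#' @param config An [ipm_scenario()].
#' @return An object of class `"ipm_truth"`: a list with the abundance array
#'   `N`, rate arrays `NS`, `HS`, `R`, `gamma`, realized harvest `H` and
#'   reported harvest `Hrep` (all integer arrays, `Hrep <= H <= N`), and the
#'   generating `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "ipm_scenario"))
  idx <- config$idx
  tr <- config$true_rates
  set.seed(config$seed)

  eps <- function(sigma) matrix(stats::rnorm(idx$T * idx$I, 0, sigma),
                                idx$T, idx$I)
  NS <- assemble_rate(tr$mu_NS, tr$lhr_NS, eps(tr$sigma_NS), idx)
  HS <- assemble_rate(tr$mu_HS, tr$lhr_HS, eps(tr$sigma_HS), idx)
  R  <- assemble_rate(tr$mu_R,  tr$lhr_R,  eps(tr$sigma_R),  idx)
  eps_rec <- array(stats::rnorm(2L * idx$T * idx$I, 0, tr$sigma_rec),
                   c(2L, idx$T, idx$I))
  gamma <- assemble_rate(tr$mu_rec, eps = eps_rec, idx = idx, link = "log")
  bad <- !is.finite(c(NS, HS, R, gamma))
  if (any(bad))
    stop("non-finite rate after link inversion (check baselines and offsets)",
         call. = FALSE)

  N <- H <- Hrep <- array(0L, c(idx$A, idx$T, idx$S, idx$I))
  N[, 1L, , ] <- config$initial_abundance
  for (i in seq_len(idx$I)) {
    for (t in seq_len(idx$T)) {
      for (s in seq_len(idx$S)) {
        for (a in seq_len(idx$A)) {
          H[a, t, s, i] <- stats::rbinom(1L, N[a, t, s, i], 1 - HS[a, t, s, i])
          Hrep[a, t, s, i] <- stats::rbinom(1L, H[a, t, s, i], R[a, t, s, i])
        }
      }
      if (t < idx$T) {
        for (s in seq_len(idx$S)) {
          hunt_surv <- N[, t, s, i] - H[, t, s, i]
          ann <- stats::rbinom(3L, hunt_surv, NS[, t, s, i])
          N[2L, t + 1L, s, i] <- ann[1L]
          N[3L, t + 1L, s, i] <- ann[2L] + ann[3L]
        }
        mothers <- stats::rbinom(3L, N[, t, 1L, i] - H[, t, 1L, i],
                                 NS[, t, 1L, i]^(8 / 12))
        lam <- sum(mothers * gamma[, t, i])
        for (s in seq_len(idx$S))
          N[1L, t + 1L, s, i] <- stats::rpois(1L, lam * 0.5)
      }
    }
  }
  structure(list(N = N, NS = NS, HS = HS, R = R, gamma = gamma,
                 H = H, Hrep = Hrep, config = config),
            class = "ipm_truth")
}

#' Simulate the observed data streams from a true population
#'
#' Thins the realized reported harvest into the observed streams: bag totals
#' per year/unit (Antlerless = all females + male fawns, Antlered = male
#' yearlings + adults), an aged-and-sexed subsample drawn per class as
#' Binomial(Hrep, aged_sexed_fraction), and statewide auxiliary estimates of
#' *total* harvest by bag for the declared years, drawn
#' Normal(total, (aux_cv * total)^2) truncated at 0.
#'
#' @param truth An [simulate_population()] result.
#' @param config The matching [ipm_scenario()] (defaults to `truth$config`).
#' @return A [harvest_data()] object.
#' @export
simulate_observations <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ipm_truth"), inherits(config, "ipm_scenario"))
  idx <- config$idx
  if (!all(dim(truth$Hrep) == c(idx$A, idx$T, idx$S, idx$I)))
    stop("truth and config dimensions disagree", call. = FALSE)
  set.seed(config$seed + 1L)

  y_H <- array(0, c(idx$T, 2L, idx$I))
  y_A <- array(0L, c(idx$A, idx$T, idx$S, idx$I))
  for (t in seq_len(idx$T)) for (i in seq_len(idx$I)) {
    y_H[t, , i] <- bag_expectations(truth$Hrep[, t, , i])
    for (s in seq_len(idx$S))
      y_A[, t, s, i] <- stats::rbinom(idx$A, truth$Hrep[, t, s, i],
                                      config$aged_sexed_fraction)
  }
  y_Hest <- matrix(NA_real_, idx$T, 2L)
  swH <- apply(truth$H, 1:3, sum)
  for (t in config$aux_years) {
    tot <- bag_expectations(swH[, t, ])
    y_Hest[t, ] <- pmax(stats::rnorm(2L, tot, config$aux_cv * tot), 0)
  }
  harvest_data(y_H, y_A, y_Hest, config$aux_years, config$unit_area)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: [simulate_population()] then
#' [simulate_observations()].
#'
#' @param config An [ipm_scenario()].
#' @return A list with `truth` (class `"ipm_truth"`) and `data`
#'   (class `"harvest_data"`).
#' @export
simulate_ipm <- function(config = ipm_scenario()) {
  truth <- simulate_population(config)
  list(truth = truth, data = simulate_observations(truth, config))
}
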
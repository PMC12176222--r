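# Latent ecological process model: link functions, rate assembly, and
# stage-structured projection with moment-matched normal approximations.

AGES  <- c("fawn", "yearling", "adult")
SEXES <- c("F", "M")
BAGS  <- c("Antlerless", "Antlered")

#' Index space for a stage-structured harvest model
#'
#' Defines the dimensions of every rate and abundance array used by the
#' model: three age classes (fawn ~0.5 yr, yearling ~1.5 yr, adult >= 2.5 yr
#' at a post-birth-pulse fall census), two sexes, `n_years` harvest years and
#' `n_units` management units.
#'
#' @param n_years Number of harvest years (>= 3).
#' @param n_units Number of management units (>= 1).
#' @return An object of class `"ipm_index"`: a list with elements `A`, `S`,
#'   `T`, `I` and the age/sex labels.
#' @export
ipm_index <- function(n_years, n_units) {
  n_years <- as.integer(n_years)
  n_units <- as.integer(n_units)
  if (is.na(n_years) || n_years < 3L)
    stop("n_years must be an integer >= 3", call. = FALSE)
  if (is.na(n_units) || n_units < 1L)
    stop("n_units must be an integer >= 1", call. = FALSE)
  structure(list(A = 3L, S = 2L, T = n_years, I = n_units,
                 ages = AGES, sexes = SEXES),
            class = "ipm_index")
}

#' Survival probability from a log cumulative hazard
#'
#' Inverse of the complementary log-log parameterization used for natural
#' survival, hunting survival and reporting rates: `exp(-exp(eta))`, the
#' survival probability when `eta` is the log cumulative hazard. Strictly
#' decreasing in `eta` and mapping the reals onto (0, 1); additive offsets on
#' `eta` are log hazard ratios, so adding `log(k)` raises survival to the
#' k-th power.
#'
#' @param eta Numeric vector of linear predictors (log cumulative hazard).
#' @return Survival probabilities in (0, 1) (1 in the limit `eta -> -Inf`).
#' @export
#' @examples
#' survival_from_linpred(-2.12) # ~0.887
survival_from_linpred <- function(eta) {
  if (any(is.na(eta))) stop("eta contains missing values", call. = FALSE)
  exp(-exp(eta))
}

#' Log cumulative hazard from a survival probability
#'
#' Forward complementary log-log link for survival-type rates:
#' `log(-log(p))`, the inverse of [survival_from_linpred()].
#'
#' @param p Probabilities in (0, 1).
#' @return Linear-predictor values.
#' @export
cloglog_link <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly in (0, 1)", call. = FALSE)
  log(-log(p))
}

#' Assemble a demographic rate array from its linear predictor
#'
#' Builds a rate array over (age, year, sex, unit) from a per-sex baseline
#' `mu`, age-class offsets `lhr` (log hazard ratios, reference age 0) and a
#' random-effect array `eps`. Survival-type rates (natural survival, hunting
#' survival, reporting) use the log-cumulative-hazard link,
#' `rate = exp(-exp(mu[s] + lhr[a] + eps[t, i]))`; recruitment uses a log
#' link, `gamma = exp(mu + eps[a, t, i])`, with the fawn class forced to 0
#' (fawns do not reproduce in this model).
#'
#' @param mu Baseline: length-`S` numeric for the cloglog link (one per sex),
#'   or a single numeric for the log link.
#' @param lhr Length-`A` age offsets (reference age must be 0). Ignored for
#'   the log link.
#' @param eps Random effects: a `T x I` matrix shared across ages and sexes
#'   for the cloglog link, or a `2 x T x I` array (yearling, adult) for the
#'   log link.
#' @param idx An [ipm_index()].
#' @param link `"cloglog-survival"` or `"log"`.
#' @return For `"cloglog-survival"`, an `A x T x S x I` array of
#'   probabilities; for `"log"`, an `A x T x I` array of recruitment rates
#'   with the fawn slice 0.
#' @export
assemble_rate <- function(mu, lhr = NULL, eps, idx,
                          link = c("cloglog-survival", "log")) {
  link <- match.arg(link)
  stopifnot(inherits(idx, "ipm_index"))
  if (link == "cloglog-survival") {
    if (length(mu) != idx$S)
      stop("mu must have one entry per sex (axis 'sex')", call. = FALSE)
    if (is.null(lhr) || length(lhr) != idx$A)
      stop("lhr must have one entry per age class (axis 'age')", call. = FALSE)
    eps <- as.matrix(eps)
    if (!all(dim(eps) == c(idx$T, idx$I)))
      stop(sprintf("eps must be a %d x %d matrix (axes 'year' x 'unit')",
                   idx$T, idx$I), call. = FALSE)
    eta <- array(0, c(idx$A, idx$T, idx$S, idx$I))
    for (s in seq_len(idx$S))
      for (i in seq_len(idx$I))
        eta[, , s, i] <- mu[s] + outer(lhr, eps[, i], "+")
    survival_from_linpred(eta)
  } else {
    if (length(mu) != 1L)
      stop("log-link baseline mu must be scalar", call. = FALSE)
    if (!is.array(eps) || !all(dim(eps) == c(2L, idx$T, idx$I)))
      stop(sprintf("eps must be a 2 x %d x %d array (axes 'age' x 'year' x 'unit')",
                   idx$T, idx$I), call. = FALSE)
    gam <- array(0, c(idx$A, idx$T, idx$I))
    gam[2L, , ] <- exp(mu + eps[1L, , ])
    gam[3L, , ] <- exp(mu + eps[2L, , ])
    gam
  }
}

#' Moment-matched normal approximation of a binomial
#'
#' Returns the mean and variance of Binomial(n, p), the moments used by the
#' model's normal approximation of binomial survival and harvest transitions.
#' The variance is floored at a small positive constant so the implied normal
#' density remains proper when `p` is 0 or 1 or `n` is 0.
#'
#' @param n Number of trials (nonnegative real; latent abundance is
#'   continuous in this model).
#' @param p Success probability in \[0, 1\].
#' @param var_floor Variance floor, default `1e-6`.
#' @return A list with elements `mean` (`n * p`) and `variance`
#'   (`max(n * p * (1 - p), var_floor)`), vectorized over inputs.
#' @export
moment_matched_binomial <- function(n, p, var_floor = 1e-6) {
  if (any(!is.finite(n)) || any(n < 0))
    stop("n must be finite and nonnegative", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  list(mean = n * p, variance = pmax(n * p * (1 - p), var_floor))
}

#' Moment-matched normal approximation of a Poisson
#'
#' @param lambda Nonnegative intensity.
#' @param var_floor Variance floor, default `1e-6`.
#' @return A list with elements `mean` (`lambda`) and `variance`
#'   (`max(lambda, var_floor)`).
#' @export
moment_matched_poisson <- function(lambda, var_floor = 1e-6) {
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop("lambda must be finite and nonnegative", call. = FALSE)
  list(mean = lambda, variance = pmax(lambda, var_floor))
}

#' Yearling projection moments
#'
#' Moments of next year's yearling abundance given the previous fall's fawn
#' abundance: survivors of both the hunting season (`HS`) and natural
#' mortality (`NS`), i.e. Binomial(N, HS * NS) moment-matched to a normal.
#'
#' @param N_fawn_prev Fawn abundance in the previous fall.
#' @param HS,NS Hunting and natural survival probabilities for fawns over
#'   that interval.
#' @param var_floor Variance floor.
#' @return A list with `mean` and `variance`.
#' @export
project_yearlings <- function(N_fawn_prev, HS, NS, var_floor = 1e-6) {
  moment_matched_binomial(N_fawn_prev, HS * NS, var_floor)
}

#' Adult projection moments
#'
#' Next year's adults are the surviving yearlings plus surviving adults, each
#' an independent binomial with its own age-class rates; means and variances
#' add.
#'
#' @param N_yearling_prev,N_adult_prev Previous-fall abundances.
#' @param HS_yearling,NS_yearling,HS_adult,NS_adult Age-class survival rates.
#' @param var_floor Variance floor (applied per component).
#' @return A list with `mean` and `variance`.
#' @export
project_adults <- function(N_yearling_prev, N_adult_prev,
                           HS_yearling, NS_yearling, HS_adult, NS_adult,
                           var_floor = 1e-6) {
  y <- moment_matched_binomial(N_yearling_prev, HS_yearling * NS_yearling, var_floor)
  a <- moment_matched_binomial(N_adult_prev, HS_adult * NS_adult, var_floor)
  list(mean = y$mean + a$mean, variance = y$variance + a$variance)
}

#' Poisson intensity for fawn production
#'
#' Expected fawns of one sex recruited to next fall's census: females of each
#' age must survive the hunting season (`HS`) and eight months of natural
#' mortality (`NS^(8/12)`, fall census to the early-June birth pulse), then
#' produce `gamma` fawns each, split between sexes by `s_ratio`. The fawn
#' class contributes nothing because its `gamma` is 0.
#'
#' @param N_female Length-`A` female abundances in the source year.
#' @param NS,HS,gamma Length-`A` natural survival, hunting survival and
#'   recruitment (fawns per female) for those females.
#' @param s_ratio Sex ratio at birth for the target sex (0.5 = even).
#' @return The scalar Poisson intensity.
#' @export
fawn_intensity <- function(N_female, NS, HS, gamma, s_ratio) {
  stopifnot(length(N_female) == length(NS), length(NS) == length(HS),
            length(HS) == length(gamma))
  if (!all(is.finite(c(N_female, NS, HS, gamma, s_ratio))))
    stop("fawn_intensity inputs must be finite", call. = FALSE)
  sum(N_female * NS^(8 / 12) * HS * gamma) * s_ratio
}

#' Deterministic mean projection of the population
#'
#' Propagates expected abundance forward with all process variances
#' suppressed: each year's yearlings/adults are the binomial means of last
#' year's fawns/(yearlings + adults), and fawns are the Poisson intensity of
#' [fawn_intensity()]. Used for initialization and for conservation checks.
#'
#' @param N1 `A x S` matrix (or `A x S x I` array) of first-year abundance.
#' @param NS,HS `A x T x S x I` survival arrays (year-t rates govern the
#'   transition into year t + 1).
#' @param gamma `A x T x I` recruitment array.
#' @param idx An [ipm_index()].
#' @param s_ratio Length-2 sex ratio at birth, summing to 1.
#' @return An `A x T x S x I` array of expected abundance.
#' @export
project_mean <- function(N1, NS, HS, gamma, idx, s_ratio = c(0.5, 0.5)) {
  stopifnot(inherits(idx, "ipm_index"))
  if (length(dim(N1)) == 2L) N1 <- array(N1, c(idx$A, idx$S, idx$I))
  N <- array(NA_real_, c(idx$A, idx$T, idx$S, idx$I))
  N[, 1L, , ] <- N1
  for (i in seq_len(idx$I)) {
    for (t in seq_len(idx$T - 1L)) {
      for (s in seq_len(idx$S)) {
        N[2L, t + 1L, s, i] <-
          project_yearlings(N[1L, t, s, i], HS[1L, t, s, i], NS[1L, t, s, i])$mean
        N[3L, t + 1L, s, i] <-
          project_adults(N[2L, t, s, i], N[3L, t, s, i],
                         HS[2L, t, s, i], NS[2L, t, s, i],
                         HS[3L, t, s, i], NS[3L, t, s, i])$mean
        N[1L, t + 1L, s, i] <-
          fawn_intensity(N[, t, 1L, i], NS[, t, 1L, i], HS[, t, 1L, i],
                         gamma[, t, i], s_ratio[s])
      }
    }
  }
  N
}

#' Stable stage-and-sex distribution at fixed rates
#'
#' Power-iterates the two-sex, three-stage projection map at constant rates
#' until the stage distribution converges, returning the share of each
#' (age, sex) class and the asymptotic growth rate. Used to apportion the
#' initial-abundance prior across classes.
#'
#' @param NS,HS `A x S` matrices of survival rates.
#' @param gamma Length-`A` recruitment rates (fawns per female).
#' @param s_ratio Length-2 sex ratio at birth.
#' @param iter Number of power iterations.
#' @return A list with `shares` (an `A x S` matrix summing to 1) and
#'   `lambda` (asymptotic annual growth rate).
#' @export
stable_stage_distribution <- function(NS, HS, gamma, s_ratio = c(0.5, 0.5),
                                      iter = 400L) {
  NS <- as.matrix(NS); HS <- as.matrix(HS)
  stopifnot(all(dim(NS) == c(3L, 2L)), all(dim(HS) == c(3L, 2L)),
            length(gamma) == 3L)
  n <- matrix(1, 3L, 2L)
  lambda <- 1
  for (k in seq_len(iter)) {
    nn <- matrix(0, 3L, 2L)
    for (s in 1:2) {
      nn[2L, s] <- n[1L, s] * HS[1L, s] * NS[1L, s]
      nn[3L, s] <- n[2L, s] * HS[2L, s] * NS[2L, s] +
                   n[3L, s] * HS[3L, s] * NS[3L, s]
      nn[1L, s] <- fawn_intensity(n[, 1L], NS[, 1L], HS[, 1L], gamma, s_ratio[s])
    }
    lambda <- sum(nn) / sum(n)
    n <- nn / sum(nn)
  }
  list(shares = n, lambda = lambda)
}
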
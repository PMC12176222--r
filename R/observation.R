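# Observation process: the three harvest data streams and their likelihood
# contributions.

#' Harvest dataset container
#'
#' Bundles the observed data streams the model is fit to: total reported
#' harvest by bag type and unit (`y_H`), the aged-and-sexed subset of the
#' reported harvest (`y_A`), optional statewide auxiliary estimates of total
#' harvest (`y_Hest`, e.g. from hunter surveys) for a declared subset of
#' years, and unit areas for densities. Bag types are `Antlerless` (all
#' females plus male fawns) and `Antlered` (male yearlings and adults).
#'
#' @param y_H `T x 2 x I` array of nonnegative reported-harvest counts
#'   (year, bag, unit).
#' @param y_A `3 x T x 2 x I` array of aged-and-sexed counts
#'   (age, year, sex, unit).
#' @param y_Hest Optional `T x 2` matrix of statewide total-harvest
#'   estimates; rows outside `aux_years` must be `NA`.
#' @param aux_years Integer years (1..T) for which `y_Hest` is available.
#' @param unit_area Length-`I` positive areas in km^2.
#' @param years,units Optional calendar-year and unit labels.
#' @return An object of class `"harvest_data"`.
#' @export
harvest_data <- function(y_H, y_A, y_Hest = NULL, aux_years = integer(),
                         unit_area, years = NULL, units = NULL) {
  stopifnot(length(dim(y_H)) == 3L, dim(y_H)[2L] == 2L,
            length(dim(y_A)) == 4L, dim(y_A)[1L] == 3L, dim(y_A)[3L] == 2L)
  T <- dim(y_H)[1L]; I <- dim(y_H)[3L]
  if (!all(dim(y_A) == c(3L, T, 2L, I)))
    stop("y_A dimensions do not match y_H (axes age x year x sex x unit)",
         call. = FALSE)
  if (any(y_H < 0) || any(y_A < 0))
    stop("harvest counts must be nonnegative", call. = FALSE)
  if (length(unit_area) != I || any(unit_area <= 0))
    stop("unit_area must be length I and positive", call. = FALSE)
  aux_years <- sort(unique(as.integer(aux_years)))
  if (length(aux_years) && (min(aux_years) < 1L || max(aux_years) > T))
    stop("aux_years must be a subset of 1..n_years", call. = FALSE)
  if (is.null(y_Hest)) {
    y_Hest <- matrix(NA_real_, T, 2L)
  } else {
    y_Hest <- as.matrix(y_Hest)
    stopifnot(all(dim(y_Hest) == c(T, 2L)))
    if (any(stats::na.omit(c(y_Hest)) < 0))
      stop("auxiliary estimates must be nonnegative", call. = FALSE)
  }
  idx <- ipm_index(T, I)
  if (is.null(years)) years <- seq_len(T)
  if (is.null(units)) units <- paste0("U", seq_len(I))
  dimnames(y_H) <- list(NULL, BAGS, units)
  dimnames(y_A) <- list(AGES, NULL, SEXES, units)
  structure(list(y_H = y_H, y_A = y_A, y_Hest = y_Hest,
                 aux_years = aux_years, unit_area = unname(unit_area),
                 years = years, units = units, idx = idx),
            class = "harvest_data")
}

#' @export
print.harvest_data <- function(x, ...) {
  cat("Harvest dataset:", x$idx$T, "years x", x$idx$I, "units\n")
  cat("  reported harvest (mean/unit/year):",
      round(mean(apply(x$y_H, c(1, 3), sum))), "\n")
  cat("  aged-sexed fraction of reported harvest:",
      signif(sum(x$y_A) / sum(x$y_H), 3), "\n")
  cat("  auxiliary estimates:",
      if (length(x$aux_years)) paste("years", paste(x$aux_years, collapse = ", "))
      else "none", "\n")
  invisible(x)
}

#' Total (unobserved) harvest
#'
#' `H = N * (1 - HS)`: the animals of a class that did not survive the
#' hunting season.
#'
#' @param N Abundance (>= 0).
#' @param HS Hunting-season survival in (0, 1).
#' @return Total harvest.
#' @export
total_harvest <- function(N, HS) {
  if (any(N < 0)) stop("N must be nonnegative", call. = FALSE)
  if (any(HS <= 0) || any(HS >= 1))
    stop("HS must lie strictly in (0, 1)", call. = FALSE)
  N * (1 - HS)
}

#' Reported harvest
#'
#' `Hrep = H * R`: harvested animals that enter the reporting system.
#'
#' @param H Total harvest (>= 0).
#' @param R Reporting rate in (0, 1).
#' @return Reported harvest.
#' @export
reported_harvest <- function(H, R) {
  if (any(H < 0)) stop("H must be nonnegative", call. = FALSE)
  if (any(R <= 0) || any(R >= 1))
    stop("R must lie strictly in (0, 1)", call. = FALSE)
  H * R
}

#' Expected reported harvest by bag type
#'
#' Collapses a reported-harvest slice over age and sex into the two bag
#' categories: Antlerless = all females plus male fawns; Antlered = male
#' yearlings plus male adults. These are the means (and, by the Poisson
#' moment match, the variances) of the normal likelihood for the observed
#' bag totals.
#'
#' @param Hrep `3 x 2` matrix (age x sex) of reported harvest for one
#'   year/unit.
#' @return Named vector `c(Antlerless, Antlered)`.
#' @export
bag_expectations <- function(Hrep) {
  Hrep <- as.matrix(Hrep)
  stopifnot(all(dim(Hrep) == c(3L, 2L)))
  c(Antlerless = sum(Hrep[, 1L]) + Hrep[1L, 2L],
    Antlered = Hrep[2L, 2L] + Hrep[3L, 2L])
}

#' Age composition of the reported harvest
#'
#' `P[a] = Hrep[a] / sum(Hrep)` within one sex/year/unit; a small additive
#' constant in numerator and denominator guards the degenerate all-zero
#' cell without breaking the simplex constraint.
#'
#' @param Hrep Length-3 nonnegative reported harvest by age.
#' @param eps Additive guard constant.
#' @return Length-3 proportions summing to 1.
#' @export
age_composition <- function(Hrep, eps = 1e-10) {
  if (any(Hrep < 0)) stop("Hrep must be nonnegative", call. = FALSE)
  (Hrep + eps) / (sum(Hrep) + length(Hrep) * eps)
}

#' Multinomial log-likelihood of aged-and-sexed counts
#'
#' The age-at-harvest likelihood: counts for one sex/year/unit are
#' multinomial with the model's age-composition proportions and size equal
#' to the observed aged-sexed sample size.
#'
#' @param y_A Length-3 nonnegative integer counts by age.
#' @param P Length-3 probability simplex (tolerance 1e-8).
#' @return The multinomial log-probability (0 for an empty sample).
#' @export
age_at_harvest_loglik <- function(y_A, P) {
  if (length(y_A) != length(P))
    stop("y_A and P lengths differ", call. = FALSE)
  if (any(P < -1e-8) || abs(sum(P) - 1) > 1e-8)
    stop("P is not a probability simplex (tolerance 1e-8)", call. = FALSE)
  if (sum(y_A) == 0) return(0)
  stats::dmultinom(y_A, prob = P, log = TRUE)
}

#' Normal log-density for an auxiliary total-harvest estimate
#'
#' Auxiliary estimates (e.g. hunter surveys) are modeled as normal around
#' the model's *total* harvest by bag (not the reported harvest) with
#' observation SD `sigma_Hest`.
#'
#' @param y_Hest Observed estimate.
#' @param total Model total harvest for that year/bag.
#' @param sigma_Hest Observation SD (> 0).
#' @return Log-density.
#' @export
aux_estimate_loglik <- function(y_Hest, total, sigma_Hest) {
  if (!is.finite(sigma_Hest) || sigma_Hest <= 0)
    stop("sigma_Hest must be positive", call. = FALSE)
  sum(stats::dnorm(y_Hest, total, sigma_Hest, log = TRUE))
}

#' Harvest state implied by abundance and rates
#'
#' Applies the observation equations elementwise: total harvest
#' `H = N (1 - HS)`, reported harvest `Hrep = H R`, and the per-sex age
#' composition `P`.
#'
#' @param N `A x T x S x I` latent abundance.
#' @param HS,R Matching hunting-survival and reporting-rate arrays.
#' @return A list with arrays `H`, `Hrep` and `P` (the latter normalized
#'   over ages within sex/year/unit).
#' @export
harvest_state <- function(N, HS, R) {
  H <- total_harvest(N, HS)
  Hrep <- reported_harvest(H, R)
  P <- Hrep
  d <- dim(Hrep)
  for (t in seq_len(d[2L])) for (s in seq_len(d[3L])) for (i in seq_len(d[4L]))
    P[, t, s, i] <- age_composition(Hrep[, t, s, i])
  list(H = H, Hrep = Hrep, P = P)
}

#' Statewide harvest state
#'
#' Sums the unit-level reported and total harvest over units, giving the
#' state-scale series to which the same bag-total and age-composition
#' likelihoods are applied.
#'
#' @param state A [harvest_state()] list.
#' @return A list with `H` and `Hrep` as `A x T x S` arrays and `P`
#'   normalized within sex/year.
#' @export
statewide_series <- function(state) {
  H <- apply(state$H, 1:3, sum)
  Hrep <- apply(state$Hrep, 1:3, sum)
  P <- Hrep
  d <- dim(Hrep)
  for (t in seq_len(d[2L])) for (s in seq_len(d[3L]))
    P[, t, s] <- age_composition(Hrep[, t, s])
  list(H = H, Hrep = Hrep, P = P)
}

# Normal log-density with Poisson moment matching (variance = mean, floored).
.poisson_normal_ll <- function(y, m, var_floor = 1e-6) {
  sum(stats::dnorm(y, m, sqrt(pmax(m, var_floor)), log = TRUE))
}

#' Observed-data log-likelihood of the integrated model
#'
#' Evaluates the joint log-likelihood of all data streams at given latent
#' abundance and rates: unit-level bag totals (normal, Poisson moment
#' match), unit-level age-at-harvest (multinomial), the same two terms on
#' the statewide sums (toggleable), and the auxiliary total-harvest
#' estimates (normal with SD `sigma_Hest`). The streams are additive;
#' disabling one removes exactly its term.
#'
#' @param dataset A [harvest_data()] object.
#' @param N `A x T x S x I` latent abundance.
#' @param HS,R Rate arrays matching `N`.
#' @param sigma_Hest Auxiliary observation SD (required if the dataset has
#'   auxiliary estimates and `aux_stream` is `TRUE`).
#' @param statewide_likelihood Include the statewide terms (default `TRUE`).
#' @param aux_stream Include the auxiliary-estimate terms (default `TRUE`).
#' @return Scalar log-likelihood with attribute `"terms"` giving the
#'   per-stream contributions.
#' @export
ipm_loglik <- function(dataset, N, HS, R, sigma_Hest = NULL,
                       statewide_likelihood = TRUE, aux_stream = TRUE) {
  idx <- dataset$idx
  st <- harvest_state(N, HS, R)
  ll_bag <- 0; ll_age <- 0; ll_sw <- 0; ll_aux <- 0
  for (t in seq_len(idx$T)) for (i in seq_len(idx$I)) {
    m <- bag_expectations(st$Hrep[, t, , i])
    ll_bag <- ll_bag + .poisson_normal_ll(dataset$y_H[t, , i], m)
    for (s in seq_len(idx$S))
      ll_age <- ll_age + age_at_harvest_loglik(dataset$y_A[, t, s, i],
                                               st$P[, t, s, i])
  }
  if (statewide_likelihood && idx$I > 1L) {
    sw <- statewide_series(st)
    for (t in seq_len(idx$T)) {
      m <- bag_expectations(sw$Hrep[, t, ])
      ll_sw <- ll_sw + .poisson_normal_ll(apply(dataset$y_H[t, , , drop = FALSE],
                                                2, sum), m)
      for (s in seq_len(idx$S))
        ll_sw <- ll_sw + age_at_harvest_loglik(apply(dataset$y_A[, t, s, ,
                                                                 drop = FALSE],
                                                     1, sum), sw$P[, t, s])
    }
  }
  if (aux_stream && length(dataset$aux_years)) {
    if (is.null(sigma_Hest))
      stop("sigma_Hest required when the auxiliary stream is enabled",
           call. = FALSE)
    swH <- apply(st$H, 1:3, sum)
    for (t in dataset$aux_years) {
      tot <- bag_expectations(swH[, t, ])
      ll_aux <- ll_aux + aux_estimate_loglik(dataset$y_Hest[t, ], tot, sigma_Hest)
    }
  }
  out <- ll_bag + ll_age + ll_sw + ll_aux
  attr(out, "terms") <- c(bag = ll_bag, age = ll_age,
                          statewide = ll_sw, aux = ll_aux)
  out
}
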
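# Posterior summaries and derived quantities: medians, 90% credible
# intervals, CVs, growth rates, densities and class proportions.

#' Summarize posterior draws
#'
#' Median, equal-tailed 90% credible interval (5% and 95% quantiles,
#' linear-interpolation type 7), and coefficient of variation
#' (posterior SD / posterior mean x 100, reported only for quantities with
#' positive posterior mean).
#'
#' @param draws Numeric vector of posterior draws (>= 2), or a matrix with
#'   one column per quantity.
#' @return A data frame with columns `median`, `lower90`, `upper90`, `cv`.
#' @export
summarize_draws <- function(draws) {
  if (is.matrix(draws)) {
    out <- do.call(rbind, lapply(seq_len(ncol(draws)),
                                 function(j) summarize_draws(draws[, j])))
    rownames(out) <- colnames(draws)
    return(out)
  }
  if (length(draws) < 2L) stop("need at least 2 draws", call. = FALSE)
  q <- stats::quantile(draws, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  mu <- mean(draws)
  data.frame(median = q[2L], lower90 = q[1L], upper90 = q[3L],
             cv = if (mu > 0) stats::sd(draws) / mu * 100 else NA_real_)
}

#' Annual growth rates and their geometric mean
#'
#' `lambda[t] = N[t + 1] / N[t]` and the geometric mean growth rate over
#' the series, `(prod(lambda))^(1/(T-1)) = (N[T] / N[1])^(1/(T-1))`.
#'
#' @param N_total Positive abundance series.
#' @return A list with `lambda` (length T - 1) and `geometric_mean`.
#' @export
growth_rates <- function(N_total) {
  if (any(!is.finite(N_total)) || any(N_total <= 0))
    stop("N_total must be positive and finite", call. = FALSE)
  T <- length(N_total)
  if (T < 2L) stop("need at least 2 years", call. = FALSE)
  lambda <- N_total[-1L] / N_total[-T]
  list(lambda = lambda,
       geometric_mean = (N_total[T] / N_total[1L])^(1 / (T - 1L)))
}

#' Population density
#'
#' Animals per square kilometre.
#'
#' @param N_total Abundance.
#' @param area_km2 Area in km^2 (> 0).
#' @return `N_total / area_km2`.
#' @export
#' @examples
#' population_density(890657, 109150) # ~8.16 deer per km^2
population_density <- function(N_total, area_km2) {
  if (any(!is.finite(area_km2)) || any(area_km2 <= 0))
    stop("area_km2 must be positive", call. = FALSE)
  N_total / area_km2
}

#' Proportions of age-sex classes in the population
#'
#' Per-draw shares of requested (age, sex) groups in total abundance.
#'
#' @param N_draws A draws x 3 x 2 array (age x sex per draw) of abundance.
#' @param groups Named list of groups; each element is a character vector of
#'   `"age.sex"` labels, e.g. `c("yearling.F", "adult.F")`.
#' @return A matrix of per-draw proportions, one column per group.
#' @export
class_proportions <- function(N_draws,
                              groups = list(
                                females = c("yearling.F", "adult.F"),
                                males = c("yearling.M", "adult.M"))) {
  stopifnot(length(dim(N_draws)) == 3L, dim(N_draws)[2L] == 3L,
            dim(N_draws)[3L] == 2L)
  labels <- as.vector(outer(AGES, SEXES, paste, sep = "."))
  flat <- matrix(N_draws, nrow = dim(N_draws)[1L],
                 dimnames = list(NULL, labels))
  total <- rowSums(flat)
  if (any(total <= 0)) stop("total abundance must be positive", call. = FALSE)
  out <- vapply(groups, function(g) {
    if (!all(g %in% labels))
      stop("unknown class labels: ",
           paste(setdiff(g, labels), collapse = ", "), call. = FALSE)
    rowSums(flat[, g, drop = FALSE]) / total
  }, numeric(length(total)))
  colnames(out) <- names(groups)
  out
}

# ---- extraction helpers on fitted objects --------------------------------

# Combined draws matrix across chains.
as_draws_matrix <- function(fit) {
  do.call(rbind, lapply(fit$samples, as.matrix))
}

#' Extract posterior draws of a monitored array
#'
#' Parses the JAGS column names (`"N[1,2,1,1]"` etc.) of a monitored node
#' back into an array with a leading draw dimension.
#'
#' @param fit A fitted `"harvest_ipm"` object.
#' @param name Monitored node name, e.g. `"N"`, `"Hrep"`, `"H"`.
#' @return An array `draws x dim1 x dim2 x ...`.
#' @export
extract_array <- function(fit, name) {
  draws <- as_draws_matrix(fit)
  cols <- grep(paste0("^", name, "\\["), colnames(draws), value = TRUE)
  if (!length(cols)) stop("node '", name, "' was not monitored", call. = FALSE)
  idx <- do.call(rbind, lapply(strsplit(sub("\\]$", "",
                                            sub("^[^\\[]+\\[", "", cols)), ","),
                               as.integer))
  d <- apply(idx, 2, max)
  out <- array(NA_real_, c(nrow(draws), d))
  for (j in seq_along(cols))
    out[cbind(seq_len(nrow(draws)),
              matrix(idx[j, ], nrow(draws), ncol(idx), byrow = TRUE))] <-
      draws[, cols[j]]
  out
}

#' Posterior draws of total abundance
#'
#' @param fit A fitted `"harvest_ipm"` object.
#' @param scope `"statewide"` (sum over units) or `"unit"` (per unit).
#' @return For `"statewide"`, a draws x T matrix; for `"unit"`, a
#'   draws x T x I array.
#' @export
total_abundance <- function(fit, scope = c("statewide", "unit")) {
  scope <- match.arg(scope)
  N <- extract_array(fit, "N") # draws x A x T x S x I
  if (scope == "statewide") apply(N, c(1, 3), sum) else apply(N, c(1, 3, 5), sum)
}

#' Posterior summary of annual growth rates
#'
#' Applies [growth_rates()] to each posterior draw of the total-abundance
#' trajectory and summarizes the annual rates and their geometric mean.
#'
#' @param fit A fitted `"harvest_ipm"` object.
#' @param scope `"statewide"` or `"unit"`.
#' @param unit Unit index when `scope = "unit"`.
#' @return A list with `lambda` (a summary data frame per transition) and
#'   `geometric_mean` (a one-row summary data frame).
#' @export
growth_summary <- function(fit, scope = c("statewide", "unit"), unit = 1L) {
  scope <- match.arg(scope)
  Nt <- if (scope == "statewide") total_abundance(fit, "statewide")
        else total_abundance(fit, "unit")[, , unit]
  gr <- apply(Nt, 1, growth_rates)
  lam <- t(vapply(gr, `[[`, numeric(ncol(Nt) - 1L), "lambda"))
  if (ncol(Nt) == 2L) lam <- t(lam)
  gm <- vapply(gr, `[[`, numeric(1), "geometric_mean")
  list(lambda = summarize_draws(lam), geometric_mean = summarize_draws(gm))
}
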
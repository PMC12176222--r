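# S3 methods for fitted "harvest_ipm" objects.

# Hyperparameter columns (everything that is not a latent array).
.hyper_cols <- function(fit) {
  cols <- colnames(as.matrix(fit$samples[[1]]))
  cols[!grepl("^(N|Hrep|H)\\[", cols)]
}

#' @export
print.harvest_ipm <- function(x, ...) {
  cat("Integrated population model fit (harvest data only)\n")
  cat("  data: ", x$idx$T, " years x ", x$idx$I, " units; streams: bag totals,",
      " age-at-harvest", if (x$model$aux_stream) ", auxiliary estimates",
      if (x$model$statewide_likelihood) ", statewide sums", "\n", sep = "")
  cat("  chains:", length(x$samples),
      "| retained draws/chain:", nrow(x$samples[[1]]),
      "| total iterations/chain:", x$total_iterations, "\n")
  cat("  converged:", x$converged,
      sprintf("(max split-Rhat %.3f, threshold %.2f)\n",
              max(x$rhat, na.rm = TRUE), x$control$rhat_threshold))
  Nt <- total_abundance(x)
  s <- summarize_draws(Nt[, ncol(Nt)])
  cat(sprintf("  final-year total abundance: %s (90%% CRI %s-%s)\n",
              format(round(s$median), big.mark = ","),
              format(round(s$lower90), big.mark = ","),
              format(round(s$upper90), big.mark = ",")))
  invisible(x)
}

#' Summarize a fitted integrated population model
#'
#' @param object A fitted `"harvest_ipm"`.
#' @param pars Optional regular expression selecting parameters (default:
#'   all hyperparameters plus statewide annual abundance).
#' @param ... Unused.
#' @return A data frame with `parameter`, `median`, `lower90`, `upper90`,
#'   `cv`, `rhat`.
#' @export
summary.harvest_ipm <- function(object, pars = NULL, ...) {
  draws <- as_draws_matrix(object)
  cols <- .hyper_cols(object)
  tab <- summarize_draws(draws[, cols, drop = FALSE])
  Nt <- total_abundance(object)
  colnames(Nt) <- paste0("Ntotal[", seq_len(ncol(Nt)), "]")
  tab <- rbind(tab, summarize_draws(Nt))
  out <- data.frame(parameter = rownames(tab), tab, row.names = NULL)
  out$rhat <- unname(object$rhat[out$parameter])
  if (!is.null(pars)) out <- out[grepl(pars, out$parameter), ]
  out
}

#' Posterior median demographic-rate baselines
#'
#' Baseline (adult, random effects at zero) natural survival, hunting
#' survival, reporting and recruitment rates on the response scale, by sex.
#'
#' @param object A fitted `"harvest_ipm"`.
#' @param ... Unused.
#' @return Named numeric vector of posterior medians.
#' @export
coef.harvest_ipm <- function(object, ...) {
  draws <- as_draws_matrix(object)
  med <- function(p) stats::median(draws[, p])
  c(NS.F = survival_from_linpred(med("mu.NS[1]")),
    NS.M = survival_from_linpred(med("mu.NS[2]")),
    HS.F = survival_from_linpred(med("mu.HS[1]")),
    HS.M = survival_from_linpred(med("mu.HS[2]")),
    R.F = survival_from_linpred(med("mu.R[1]")),
    R.M = survival_from_linpred(med("mu.R[2]")),
    recruitment = exp(med("mu.rec")))
}

#' Plot the estimated abundance trajectory
#'
#' Posterior median total abundance with the equal-tailed 90% credible band,
#' statewide or for one unit.
#'
#' @param x A fitted `"harvest_ipm"`.
#' @param scope `"statewide"` or `"unit"`.
#' @param unit Unit index when `scope = "unit"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the summary data frame plotted.
#' @export
plot.harvest_ipm <- function(x, scope = c("statewide", "unit"), unit = 1L,
                             ...) {
  scope <- match.arg(scope)
  Nt <- if (scope == "statewide") total_abundance(x, "statewide")
        else total_abundance(x, "unit")[, , unit]
  s <- summarize_draws(Nt)
  yrs <- x$dataset$years
  graphics::plot(yrs, s$median, type = "n",
                 ylim = range(s$lower90, s$upper90),
                 xlab = "Year", ylab = "Total abundance", ...)
  graphics::polygon(c(yrs, rev(yrs)), c(s$lower90, rev(s$upper90)),
                    col = "grey85", border = NA)
  graphics::lines(yrs, s$median, lwd = 2)
  invisible(s)
}

#' Simulate replicate datasets from the posterior predictive distribution
#'
#' Draws replicate observed datasets (bag totals, aged-sexed counts and,
#' when present, auxiliary estimates) from the observation model at
#' posterior draws of the latent harvest state.
#'
#' @param object A fitted `"harvest_ipm"`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of [harvest_data()] objects.
#' @export
simulate.harvest_ipm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dataset <- object$dataset
  idx <- object$idx
  Hrep <- extract_array(object, "Hrep")
  has_aux <- length(dataset$aux_years) > 0 && object$model$aux_stream
  if (has_aux) {
    H <- extract_array(object, "H")
    sig <- as_draws_matrix(object)[, "sigma.Hest"]
  }
  nA <- apply(dataset$y_A, c(2, 3, 4), sum)
  picks <- sample.int(dim(Hrep)[1L], nsim, replace = TRUE)
  lapply(picks, function(j) {
    y_H <- array(0, c(idx$T, 2L, idx$I))
    y_A <- array(0L, c(idx$A, idx$T, 2L, idx$I))
    for (t in seq_len(idx$T)) for (i in seq_len(idx$I)) {
      m <- bag_expectations(Hrep[j, , t, , i])
      y_H[t, , i] <- pmax(stats::rnorm(2L, m, sqrt(pmax(m, 1e-6))), 0)
      for (s in 1:2) if (nA[t, s, i] > 0)
        y_A[, t, s, i] <- stats::rmultinom(1L, nA[t, s, i],
                                           age_composition(Hrep[j, , t, s, i]))[, 1L]
    }
    y_Hest <- matrix(NA_real_, idx$T, 2L)
    if (has_aux) for (t in dataset$aux_years) {
      tot <- bag_expectations(apply(H[j, , t, , , drop = FALSE], c(2, 4), sum))
      y_Hest[t, ] <- pmax(stats::rnorm(2L, tot, sig[j]), 0)
    }
    harvest_data(y_H, y_A, y_Hest, dataset$aux_years, dataset$unit_area,
                 years = dataset$years, units = dataset$units)
  })
}

#' Posterior median expected reported harvest by bag type
#'
#' @param object A fitted `"harvest_ipm"`.
#' @param ... Unused.
#' @return A `T x 2 x I` array of posterior median bag-total expectations.
#' @export
fitted.harvest_ipm <- function(object, ...) {
  idx <- object$idx
  Hrep <- extract_array(object, "Hrep")
  m <- array(NA_real_, c(idx$T, 2L, idx$I),
             dimnames = list(NULL, BAGS, object$dataset$units))
  for (t in seq_len(idx$T)) for (i in seq_len(idx$I)) {
    bags <- t(apply(Hrep[, , t, , i], 1, bag_expectations))
    m[t, , i] <- apply(bags, 2, stats::median)
  }
  m
}

#' Pearson residuals of the bag-total stream
#'
#' `(y - m) / sqrt(m)` at the posterior median expectations, the natural
#' residual under the Poisson moment match.
#'
#' @param object A fitted `"harvest_ipm"`.
#' @param ... Unused.
#' @return A `T x 2 x I` array of residuals.
#' @export
residuals.harvest_ipm <- function(object, ...) {
  m <- fitted(object)
  (object$dataset$y_H - m) / sqrt(pmax(m, 1e-6))
}
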
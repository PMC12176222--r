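# Convergence assessment: the Gelman-Rubin potential scale reduction
# factor, classic and split-chain variants.

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic estimator for a scalar quantity monitored on two or more chains
#' of equal length n: with W the mean within-chain variance and B the
#' between-chain variance (n times the variance of the chain means),
#' `Rhat = sqrt(((n - 1) / n * W + B / n) / W)`. If every chain has zero
#' within-chain variance the statistic is defined as 1.
#'
#' @param chains A list of equal-length numeric vectors, or an
#'   iterations-by-chains matrix.
#' @return The scalar potential scale reduction factor.
#' @export
#' @examples
#' gelman_rubin(list(c(1, 2, 3), c(1, 2, 3))) # sqrt(2/3)
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2L) stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length", call. = FALSE)
  if (n < 2L) stop("need at least 2 draws per chain", call. = FALSE)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (W == 0) return(1)
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split-chain Rhat
#'
#' The split-chain refinement: each chain is halved and [gelman_rubin()] is
#' applied to the 2m half-chains, so within-chain trends (a chain drifting
#' but the chains agreeing) also inflate the statistic.
#'
#' @inheritParams gelman_rubin
#' @return The scalar split-chain potential scale reduction factor.
#' @export
split_rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  half <- function(x) {
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[seq_len(n2) + (length(x) - n2)])
  }
  gelman_rubin(unlist(lapply(chains, half), recursive = FALSE))
}

# Split-Rhat for every monitored column of an mcmc.list.
rhat_all <- function(samples) {
  mats <- lapply(samples, as.matrix)
  vapply(colnames(mats[[1]]), function(p)
    split_rhat(lapply(mats, function(m) m[, p])), numeric(1))
}
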
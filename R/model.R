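# Joint-model assembly: translates the process and observation equations
# plus the prior set into JAGS model code, data, and initial values.

# Model code is assembled from blocks so the statewide and auxiliary
# likelihood terms can be toggled without string surgery elsewhere.
ipm_model_code <- function(statewide, aux) {
  core <- "
model {
  # --- hyperpriors -------------------------------------------------------
  for (s in 1:2) {
    mu.NS[s] ~ dnorm(pm.NS[s], 1 / pow(ps.NS[s], 2))
    mu.HS[s] ~ dnorm(pm.HS[s], 1 / pow(ps.HS[s], 2))
    mu.R[s]  ~ dnorm(pm.R[s],  1 / pow(ps.R[s],  2))
  }
  mu.rec ~ dnorm(pm.rec, 1 / pow(ps.rec, 2))
  for (a in 1:2) {
    lhr.NS[a] ~ dnorm(plhr.NS[1], 1 / pow(plhr.NS[2], 2))
    lhr.HS[a] ~ dnorm(plhr.HS[1], 1 / pow(plhr.HS[2], 2))
    lhr.R[a]  ~ dnorm(plhr.R[1],  1 / pow(plhr.R[2],  2))
  }
  lhr.NS[3] <- 0
  lhr.HS[3] <- 0
  lhr.R[3]  <- 0
  sig.NS  ~ dgamma(g.NS[1],  g.NS[2])
  sig.HS  ~ dgamma(g.HS[1],  g.HS[2])
  sig.R   ~ dgamma(g.R[1],   g.R[2])
  sig.rec ~ dgamma(g.rec[1], g.rec[2])

  # --- random effects (shared across ages and sexes) ---------------------
  for (i in 1:I) {
    for (t in 1:TY) {
      eps.HS[t, i] ~ dnorm(0, 1 / pow(sig.HS, 2))
      eps.R[t, i]  ~ dnorm(0, 1 / pow(sig.R, 2))
    }
    for (t in 1:(TY - 1)) {
      eps.NS[t, i] ~ dnorm(0, 1 / pow(sig.NS, 2))
      for (a in 1:2) { eps.rec[a, t, i] ~ dnorm(0, 1 / pow(sig.rec, 2)) }
    }
  }

  # --- rates on the response scale ---------------------------------------
  for (i in 1:I) {
    for (t in 1:TY) { for (s in 1:2) { for (a in 1:3) {
      HS[a, t, s, i] <- exp(-exp(mu.HS[s] + lhr.HS[a] + eps.HS[t, i]))
      R[a, t, s, i]  <- exp(-exp(mu.R[s]  + lhr.R[a]  + eps.R[t, i]))
    } } }
    for (t in 1:(TY - 1)) {
      for (s in 1:2) { for (a in 1:3) {
        NS[a, t, s, i] <- exp(-exp(mu.NS[s] + lhr.NS[a] + eps.NS[t, i]))
      } }
      for (a in 2:3) { gam[a, t, i] <- exp(mu.rec + eps.rec[a - 1, t, i]) }
    }
  }

  # --- initial abundance -------------------------------------------------
  for (i in 1:I) { for (s in 1:2) { for (a in 1:3) {
    N[a, 1, s, i] ~ dlnorm(ln0[a, s, i], 1 / pow(ln.sd, 2))
  } } }

  # --- process model (moment-matched normal approximations) --------------
  for (i in 1:I) { for (t in 2:TY) {
    for (s in 1:2) {
      p2[t, s, i] <- HS[1, t - 1, s, i] * NS[1, t - 1, s, i]
      m2[t, s, i] <- N[1, t - 1, s, i] * p2[t, s, i]
      N[2, t, s, i] ~ dnorm(m2[t, s, i],
        1 / max(m2[t, s, i] * (1 - p2[t, s, i]), 1.0E-6))
      py[t, s, i] <- HS[2, t - 1, s, i] * NS[2, t - 1, s, i]
      pa[t, s, i] <- HS[3, t - 1, s, i] * NS[3, t - 1, s, i]
      m3[t, s, i] <- N[2, t - 1, s, i] * py[t, s, i] +
                     N[3, t - 1, s, i] * pa[t, s, i]
      v3[t, s, i] <- max(N[2, t - 1, s, i] * py[t, s, i] * (1 - py[t, s, i]), 1.0E-6) +
                     max(N[3, t - 1, s, i] * pa[t, s, i] * (1 - pa[t, s, i]), 1.0E-6)
      N[3, t, s, i] ~ dnorm(m3[t, s, i], 1 / v3[t, s, i])
    }
    lam[t, i] <-
      N[2, t - 1, 1, i] * pow(NS[2, t - 1, 1, i], 0.6666667) *
        HS[2, t - 1, 1, i] * gam[2, t - 1, i] +
      N[3, t - 1, 1, i] * pow(NS[3, t - 1, 1, i], 0.6666667) *
        HS[3, t - 1, 1, i] * gam[3, t - 1, i]
    for (s in 1:2) {
      N[1, t, s, i] ~ dnorm(lam[t, i] * 0.5,
        1 / max(lam[t, i] * 0.5, 1.0E-6))
    }
  } }

  # --- observation: unit-level bag totals and age composition ------------
  for (i in 1:I) { for (t in 1:TY) {
    for (s in 1:2) { for (a in 1:3) {
      H[a, t, s, i]    <- N[a, t, s, i] * (1 - HS[a, t, s, i])
      Hrep[a, t, s, i] <- H[a, t, s, i] * R[a, t, s, i]
    } }
    m.bag[t, 1, i] <- Hrep[1, t, 1, i] + Hrep[2, t, 1, i] +
                      Hrep[3, t, 1, i] + Hrep[1, t, 2, i]
    m.bag[t, 2, i] <- Hrep[2, t, 2, i] + Hrep[3, t, 2, i]
    for (b in 1:2) {
      yH[t, b, i] ~ dnorm(m.bag[t, b, i], 1 / max(m.bag[t, b, i], 1.0E-6))
    }
    for (s in 1:2) {
      den[t, s, i] <- max(Hrep[1, t, s, i], 0) + max(Hrep[2, t, s, i], 0) +
                      max(Hrep[3, t, s, i], 0) + 3.0E-10
      for (a in 1:3) {
        P[a, t, s, i] <- (max(Hrep[a, t, s, i], 0) + 1.0E-10) / den[t, s, i]
      }
    }
  } }
  for (j in 1:nAgeObs) {
    yAobs[j, 1:3] ~ dmulti(P[1:3, aT[j], aS[j], aI[j]], nA[j])
  }
"
  sw <- "
  # --- observation: statewide sums of the same streams --------------------
  for (t in 1:TY) {
    m.sw[t, 1] <- Hrep.sw[1, t, 1] + Hrep.sw[2, t, 1] +
                  Hrep.sw[3, t, 1] + Hrep.sw[1, t, 2]
    m.sw[t, 2] <- Hrep.sw[2, t, 2] + Hrep.sw[3, t, 2]
    for (b in 1:2) {
      yH.sw[t, b] ~ dnorm(m.sw[t, b], 1 / max(m.sw[t, b], 1.0E-6))
    }
    for (s in 1:2) {
      den.sw[t, s] <- max(Hrep.sw[1, t, s], 0) + max(Hrep.sw[2, t, s], 0) +
                      max(Hrep.sw[3, t, s], 0) + 3.0E-10
      for (a in 1:3) {
        P.sw[a, t, s] <- (max(Hrep.sw[a, t, s], 0) + 1.0E-10) / den.sw[t, s]
      }
    }
  }
  for (j in 1:nAgeObsSw) {
    yAsw[j, 1:3] ~ dmulti(P.sw[1:3, aTsw[j], aSsw[j]], nAsw[j])
  }
"
  sums <- "
  for (t in 1:TY) { for (s in 1:2) { for (a in 1:3) {
    Hrep.sw[a, t, s] <- sum(Hrep[a, t, s, 1:I])
    H.sw[a, t, s]    <- sum(H[a, t, s, 1:I])
  } } }
"
  auxb <- "
  # --- observation: auxiliary estimates of total harvest ------------------
  sigma.Hest ~ dnorm(0, 1 / pow(hest.scale, 2)) T(0, )
  for (k in 1:nAux) {
    tot[k, 1] <- H.sw[1, auxYear[k], 1] + H.sw[2, auxYear[k], 1] +
                 H.sw[3, auxYear[k], 1] + H.sw[1, auxYear[k], 2]
    tot[k, 2] <- H.sw[2, auxYear[k], 2] + H.sw[3, auxYear[k], 2]
    for (b in 1:2) {
      yHest[k, b] ~ dnorm(tot[k, b], 1 / pow(sigma.Hest, 2))
    }
  }
"
  paste0(core, sums, if (statewide) sw, if (aux) auxb, "\n}\n")
}

#' Assemble the joint Bayesian model
#'
#' Builds everything the sampler needs from a dataset and a prior set: the
#' model code (process model with moment-matched normal approximations,
#' the three observation streams, and all priors), the data list, the
#' monitored nodes, and a per-chain initial-values function. Chains start
#' overdispersed with baselines drawn from their priors, and each chain's
#' latent abundance is back-calculated from the first-year harvest under
#' that chain's own drawn rates, so the chains begin spread along the
#' rates-versus-abundance ridge of the posterior rather than stacked at one
#' point of it.
#'
#' @param dataset A [harvest_data()] object.
#' @param priors An [default_priors()] prior set.
#' @param statewide_likelihood Include the statewide likelihood terms
#'   (default `TRUE`; automatically off for a single-unit dataset, whose
#'   statewide series is identical to the unit series).
#' @param aux_stream Include the auxiliary-estimate terms (default `TRUE`;
#'   off if the dataset has none).
#' @param init_abundance_override Optional `A x S x I` array of prior median
#'   abundances passed to [initial_abundance_prior()].
#' @return An object of class `"ipm_model"`: a list with `code`, `data`,
#'   `monitors`, `inits` (function of chain number and seed), and the
#'   resolved toggles.
#' @export
build_joint_model <- function(dataset, priors = default_priors(),
                              statewide_likelihood = TRUE, aux_stream = TRUE,
                              init_abundance_override = NULL) {
  stopifnot(inherits(dataset, "harvest_data"), inherits(priors, "ipm_priors"))
  idx <- dataset$idx
  missing <- c(if (is.null(dataset$y_H)) "harvest totals",
               if (is.null(dataset$y_A)) "age-at-harvest counts")
  if (length(missing))
    stop("dataset is missing required streams: ",
         paste(missing, collapse = ", "), call. = FALSE)
  statewide <- statewide_likelihood && idx$I > 1L
  aux <- aux_stream && length(dataset$aux_years) > 0L

  nA <- apply(dataset$y_A, c(2, 3, 4), sum)
  obs <- which(nA > 0, arr.ind = TRUE)
  yAobs <- t(vapply(seq_len(nrow(obs)), function(j)
    dataset$y_A[, obs[j, 1L], obs[j, 2L], obs[j, 3L]], numeric(3)))
  init_prior <- initial_abundance_prior(dataset, priors,
                                        override = init_abundance_override)
  data <- list(
    TY = idx$T, I = idx$I, yH = dataset$y_H,
    nAgeObs = nrow(obs), yAobs = yAobs,
    aT = obs[, 1L], aS = obs[, 2L], aI = obs[, 3L],
    pm.NS = unname(priors$NS$location), ps.NS = unname(priors$NS$sd),
    pm.HS = unname(priors$HS$location), ps.HS = unname(priors$HS$sd),
    pm.R = unname(priors$R$location), ps.R = unname(priors$R$sd),
    pm.rec = unname(priors$rec$location[[1]]),
    ps.rec = unname(priors$rec$sd[[1]]),
    plhr.NS = unname(priors$NS$lhr), plhr.HS = unname(priors$HS$lhr),
    plhr.R = unname(priors$R$lhr),
    g.NS = unname(priors$NS$re_sd), g.HS = unname(priors$HS$re_sd),
    g.R = unname(priors$R$re_sd), g.rec = unname(priors$rec$re_sd),
    ln0 = init_prior$log_median, ln.sd = init_prior$log_sd)
  if (statewide) {
    yH_sw <- apply(dataset$y_H, 1:2, sum)
    nA_sw <- apply(dataset$y_A, c(2, 3), sum)
    obs_sw <- which(nA_sw > 0, arr.ind = TRUE)
    data$yH.sw <- yH_sw
    data$nAgeObsSw <- nrow(obs_sw)
    data$yAsw <- t(vapply(seq_len(nrow(obs_sw)), function(j)
      apply(dataset$y_A[, obs_sw[j, 1L], obs_sw[j, 2L], , drop = FALSE], 1, sum),
      numeric(3)))
    data$aTsw <- obs_sw[, 1L]; data$aSsw <- obs_sw[, 2L]
    data$nAsw <- nA_sw[obs_sw]
  }
  if (aux) {
    data$nAux <- length(dataset$aux_years)
    data$auxYear <- dataset$aux_years
    data$yHest <- dataset$y_Hest[dataset$aux_years, , drop = FALSE]
    data$hest.scale <- priors$sigma_Hest_scale_frac *
      mean(dataset$y_Hest[dataset$aux_years, ])
  }
  data$nA <- nA[obs]

  monitors <- c("mu.NS", "mu.HS", "mu.R", "mu.rec",
                "lhr.NS", "lhr.HS", "lhr.R",
                "sig.NS", "sig.HS", "sig.R", "sig.rec",
                if (aux) "sigma.Hest", "N", "Hrep", "H")

  # Chains start overdispersed along the posterior's slow direction:
  # baselines are drawn from their priors (offsets and SDs from moderate
  # spreads -- the vague LHR prior would initialize at degenerate rates),
  # and each chain's latent abundance is then back-calculated from the
  # first-year harvest under *its own* drawn rates, so every chain starts
  # on the data-consistent manifold but at a different point along the
  # rates-versus-abundance ridge.
  inits <- function(chain, seed) {
    set.seed(seed + 1000L * chain)
    jit <- function(x, s) x + stats::rnorm(length(x), 0, s)
    rgam <- function(g) stats::rgamma(1L, g[[1L]], g[[2L]])
    mu_NS <- jit(unname(priors$NS$location), unname(priors$NS$sd))
    mu_HS <- jit(unname(priors$HS$location), unname(priors$HS$sd))
    mu_R <- jit(unname(priors$R$location), unname(priors$R$sd))
    mu_rec <- jit(unname(priors$rec$location[[1]]),
                  unname(priors$rec$sd[[1]]))
    lhr_NS <- jit(c(0, 0), 0.3)
    lhr_HS <- jit(c(0, 0), 0.3)
    lhr_R <- jit(c(0, 0), 0.3)
    rate_mat <- function(mu, lhr) # A x S from drawn baselines/offsets
      vapply(1:2, function(s) survival_from_linpred(mu[s] + c(lhr, 0)),
             numeric(3))
    NSc <- rate_mat(mu_NS, lhr_NS)
    HSc <- rate_mat(mu_HS, lhr_HS)
    Rc <- rate_mat(mu_R, lhr_R)
    gamc <- c(0, rep(exp(mu_rec), 2))
    ss <- stable_stage_distribution(NSc, HSc, gamc)
    # Reporting rate for the back-calculation: when auxiliary estimates of
    # total harvest exist they identify R directly (reported / total), so
    # every chain's abundance level stays consistent with that stream;
    # otherwise the chain's own drawn R is used.
    R_hat <- if (aux) {
      ay <- dataset$aux_years
      min(sum(dataset$y_H[ay, , ]) / sum(dataset$y_Hest[ay, ]), 0.99)
    } else sum(ss$shares * (1 - HSc) * Rc) / sum(ss$shares * (1 - HSc))
    frac <- sum(ss$shares * (1 - HSc)) * R_hat
    N1 <- array(NA_real_, c(idx$A, idx$S, idx$I))
    for (i in seq_len(idx$I))
      N1[, , i] <- pmax(sum(dataset$y_H[1L, , i]) / frac, 100) * ss$shares
    const <- function(m) { # A x T x S x I constant rate array
      out <- array(NA_real_, c(idx$A, idx$T, idx$S, idx$I))
      for (s in 1:2) out[, , s, ] <- m[, s]
      out
    }
    gam0 <- array(rep(gamc, idx$T * idx$I), c(idx$A, idx$T, idx$I))
    Ninit <- project_mean(N1, const(NSc), const(HSc), gam0, idx)
    list(
      mu.NS = mu_NS,
      mu.HS = mu_HS,
      mu.R = mu_R,
      mu.rec = mu_rec,
      lhr.NS = c(lhr_NS, NA),
      lhr.HS = c(lhr_HS, NA),
      lhr.R = c(lhr_R, NA),
      sig.NS = rgam(priors$NS$re_sd),
      sig.HS = rgam(priors$HS$re_sd),
      sig.R = rgam(priors$R$re_sd),
      sig.rec = rgam(priors$rec$re_sd),
      eps.NS = matrix(0, idx$T - 1L, idx$I),
      eps.HS = matrix(0, idx$T, idx$I),
      eps.R = matrix(0, idx$T, idx$I),
      eps.rec = array(0, c(2L, idx$T - 1L, idx$I)),
      N = Ninit,
      sigma.Hest = if (aux) data$hest.scale,
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (seed + 1000L * chain) %% .Machine$integer.max)
  }
  inits_clean <- function(chain, seed) Filter(Negate(is.null), inits(chain, seed))

  structure(list(code = ipm_model_code(statewide, aux), data = data,
                 monitors = monitors, inits = inits_clean,
                 statewide_likelihood = statewide, aux_stream = aux,
                 dataset = dataset, priors = priors, idx = idx),
            class = "ipm_model")
}
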
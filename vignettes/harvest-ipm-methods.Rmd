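---
title: "Methods: an integrated population model for harvested populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrated population model for harvested populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(harvestIPM)
```

## The problem

State wildlife agencies set harvest regulations per management unit, but
abundance estimates at that scale are usually missing or imprecise. What the
agencies *do* have, every year, is harvest data: total reported harvest by bag
type, a small subsample of the reported harvest that was aged and sexed at
check stations, and occasionally survey-based estimates of total harvest.
`harvestIPM` implements a Bayesian integrated population model (IPM) that
turns those three streams — and nothing else — into estimates of abundance and
demographic rates per unit and for the whole state, by combining a
stage-structured population process with informative priors assembled from the
species' literature.

The package is written around white-tailed deer (two sexes; fawn, yearling and
adult stages; bag types Antlerless and Antlered), but every rate, stage label
and prior is an argument.

## The ecological process model

The latent state is continuous abundance $N_{a,t,s,i}$ for age class
$a \in \{\text{fawn}, \text{yearling}, \text{adult}\}$, sex $s$, year $t$ and
unit $i$, censused in mid-fall just after the birth pulse (a post-birth-pulse
census: fawns are about 0.5 years old when counted). Yearlings are the fawns
of the previous fall that survived both the hunting season (hunting survival
$HS$) and natural mortality ($NS$):

$$N_{2,t+1,s,i} \sim \text{Binomial}(N_{1,t,s,i},\; HS_{1,t,s,i} \, NS_{1,t,s,i}),$$

adults are the surviving yearlings plus surviving adults, and fawns are
Poisson around the reproductive output of surviving females:

$$N_{1,t+1,s,i} \sim \text{Poisson}\Big(\sum_a N_{a,t,1,i}\, HS_{a,t,1,i}\,
NS_{a,t,1,i}^{8/12}\, \gamma_{a,t,i}\, r_s\Big),$$

with recruitment $\gamma$ (fawns per female), an even sex ratio at birth
($r_s = 0.5$), and the $8/12$ exponent because a female censused in fall must
survive eight months of natural mortality to reach the early-June birth pulse.
Fawns do not reproduce ($\gamma_{\text{fawn}} = 0$), and units are treated as
closed (no movement terms).

**Timing convention.** Rates indexed $t$ are the rates experienced by the
year-$t$ population: the year-$t$ harvest uses $HS_{\cdot,t}$, and the
transition from fall $t$ to fall $t+1$ uses year-$t$ rates throughout. The
synthetic-data generator uses the identical convention, so generator and
likelihood describe the same process. A related open point is the $NS^{8/12}$
term: the model applies the partial-year exponent to natural survival only,
with $HS$ entering whole — the hunting season is over well before June, so
survivors of it carry no partial exposure. We implement exactly this form.

**Normal approximations.** In the likelihood, every binomial and Poisson
increment is replaced by a normal with the same mean and variance
(`moment_matched_binomial()`, `moment_matched_poisson()`), the standard
device for making latent-abundance state-space models mix and run fast. The
variance is floored at $10^{-6}$ so densities stay proper when $p \in \{0,1\}$
or $n = 0$, and latent abundance is truncated at zero. Rounding to animals
happens only in reports. The synthetic-data generator deliberately does *not*
use these approximations — it draws exact binomials and Poissons — so the
approximation error is measurable: for $n \ge 100$ and
$p \in [0.1, 0.95]$ the midpoint Kolmogorov–Smirnov distance between the
exact binomial and its moment-matched normal stays below 0.05, and the test
suite checks this numerically.

## Demographic-rate submodels

Natural survival, hunting survival and the reporting rate are modeled on the
complementary log-log scale — a time-to-event formulation in which the linear
predictor is a log cumulative hazard and survival is
$\exp(-\exp(\eta))$ (`survival_from_linpred()`):

$$\text{cloglog}(NS_{a,t,s,i}) = \mu^{NS}_s + LHR^{NS}_a + \varepsilon^{NS}_{t,i}.$$

Each rate has a per-sex baseline $\mu_s$ (the adult class), additive
age-class offsets that are log hazard ratios ($LHR$, adult reference fixed at
0, so $LHR = \log 2$ squares the baseline survival), and a year-by-unit
random effect shared across ages and sexes with an estimated SD. Recruitment
uses a log link with a single baseline and a random effect per age (yearling,
adult), year and unit. The shared $\varepsilon_{t,i}$ (rather than separate
per-sex effect fields) follows the rate equations as printed; the prior SDs
could in principle differ by sex, but one field with one SD per rate is what
the model states and is what we fit.

We resolve the cloglog orientation as survival $= \exp(-\exp(\eta))$, i.e.
$\eta$ is the log *cumulative hazard*: the default prior locations then imply
baseline survival and reporting probabilities (0.89, 0.85, 0.80, ...) that
match the magnitudes a deer biologist would expect, whereas the opposite
orientation would imply survivals near 0.1.

## Observation process

Total harvest and reported harvest are deterministic thinnings of abundance:

$$H = N (1 - HS), \qquad H^{rep} = H \cdot R,$$

with reporting rate $R$. The three data streams are:

1. **Bag totals** $y^H_{t,b,i}$: Antlerless (all females plus male fawns) and
   Antlered (male yearlings and adults) reported harvest, normal with
   variance equal to the mean (Poisson moment match).
2. **Age-at-harvest** $y^A_{a,t,s,i}$: the aged-and-sexed subsample,
   multinomial within sex over age classes with probabilities
   $P_a = H^{rep}_a / \sum_a H^{rep}_a$ and size equal to the observed
   subsample. Male fawns sit in the Antlerless bag but in the male
   composition vector. A $10^{-10}$ additive guard keeps $P$ defined when a
   cell's expected reported harvest is zero; the same guard doubles as the
   variance floor's analogue for the unstated zero-expectation corner of the
   bag-total stream.
3. **Auxiliary estimates** $y^{Hest}_{t,b}$: statewide survey estimates of
   *total* (not reported) harvest by bag, normal with estimated observation
   SD $\sigma_{Hest}$. The model never specifies a prior for $\sigma_{Hest}$
   in its source material, so the package gives it a half-normal with scale
   10% of the mean observed estimate — weak, positive, and scaled to the
   data; it is a configurable field of the prior set.

The same bag-total and age-composition likelihoods are also applied to the
statewide sums of the unit-level reported harvest. This replicates the
multiscale fit of the original analysis and is on by default
(`statewide_likelihood = TRUE`); because the statewide series is a
deterministic function of the unit-level states, it reuses the same animals
and arguably double-counts information, so the term can be switched off. For
a single-unit dataset the statewide series is identical to the unit series
and the term is dropped automatically.

## Priors

The default prior set (`default_priors()`) encodes a literature synthesis of
southeastern/midwestern deer vital rates, converted to the link scales by the
method of moments: location = link(mean), SD by the delta method
(`moments_to_link_scale()`), e.g. a survival mean 0.8868 with SD 0.025 maps
to $(-2.12, 0.235)$ on the hazard scale. The conversion is deterministic; a
Monte-Carlo transform of $10^5$ normal draws agrees within 2% for
probability-scale SDs up to 0.1, and the test suite carries that check.

| rate | female | male | RE-SD gamma |
|---|---|---|---|
| natural survival | $N(-2.12, 0.235)$ | $N(-1.60, 0.226)$ | $(0.98, 14)$ |
| hunting survival | $N(-1.80, 0.323)$ | $N(-0.96, 0.289)$ | $(3.92, 28)$ |
| reporting | $N(-1.50, 0.224)$ | $N(-1.30, 0.218)$ | $(2, 20)$ |
| recruitment (log) | $N(-0.35, 0.15)$ | — | $(5.12, 32)$ |

Age offsets ($LHR$) get vague $N(0, 10)$ priors throughout. The random-effect
SD hyperparameters are interpreted as gamma **shape and rate**: the implied
prior mean SDs (0.07, 0.14, 0.10, 0.16 on the link scale) are the magnitudes
of spatiotemporal variation one actually sees in these rates, whereas reading
the same numbers as a mean/SD pair would put the prior mass on absurd values
(e.g. a mean SD of 0.98 in hazard units for natural survival). The
interpretation is switchable (`re_sd_parameterization = "mean_sd"`) for users
whose sources tabulate moments.

**Initial abundance.** Year-1 abundance needs its own proper prior; nothing
in the harvest streams identifies it directly, and the source analysis never
states one. The package back-calculates it
(`initial_abundance_prior()`): a unit's first-year reported harvest divided
by the prior-mean harvest-and-report fraction gives a prior median total,
apportioned across the six classes by the stable stage-and-sex distribution
of the prior-mean projection, with a lognormal log-SD of 0.5 (a 90% interval
of roughly half to double). It can be overridden with an explicit array.

## Prior evaluation and widening

After a fit, `evaluate_priors()` computes the prior–posterior overlap
(`prior_posterior_overlap()`: the integral of the pointwise minimum of the
prior density and a kernel density estimate of the posterior, Silverman
bandwidth, $2^{10}$-point grid spanning both 0.001–0.999 quantile ranges).
Overlap above 0.35 — informative priors are *expected* to overlap — triggers
the data-agreement criterion (`data_agreement_criterion()`):
$\mathrm{DAC} = KL(\hat\pi \| p) / KL(\hat\pi \| p_0)$ for posterior
$\hat\pi$, prior $p$ and a benchmark prior $p_0$. DAC > 1 flags prior–data
conflict, and the remedy is mechanical: inflate the prior SD by 25%
(`widen_prior()`) and refit. The criterion's source does not name its
benchmark; we use the conventional vague same-family choice — same location,
SD × 10 — and expose the factor as an argument. The KDE route makes both
diagnostics deterministic given the draws; against closed-form normal pairs
the overlap is accurate to ~0.01 at $10^5$ draws and the DAC to ~0.01.

## Inference

`ipm_fit()` assembles the joint model (`build_joint_model()`) and samples it
with JAGS through `rjags`. We chose JAGS deliberately: with the normal
approximations the posterior is smooth, the model is a sparse hierarchical
DAG of normal, gamma and multinomial nodes — exactly the shape JAGS's
conjugate and slice samplers handle — and JAGS is the lingua franca of the
IPM literature, so the generated model code doubles as documentation. The
model's graph (not the engine) is the scientific content, and the package
also carries its own R-side observed-data log-likelihood (`ipm_loglik()`)
used by the tests to verify stream additivity and that the likelihood ranks
the generating parameters above perturbed ones.

**Initialization.** The posterior has a characteristic slow ridge: a higher
hunting hazard with proportionally more animals explains the same harvest
counts, so single-site samplers move along the rates-versus-abundance
direction very slowly. Chains are therefore started *overdispersed along
that ridge*: each chain draws its baselines from the priors (offsets and
random-effect SDs from moderate spreads; the vague $N(0,10)$ offset prior
would initialize at degenerate rates) and then back-calculates its own
initial latent-abundance trajectory from the first-year harvest under those
drawn rates. Every chain starts in a high-likelihood state, but at a
different point of the ridge — the configuration the Gelman-Rubin protocol
assumes, and the one that makes pooled short-run credible intervals
conservative rather than spuriously narrow. (Near-identical inits were
measurably anticonservative in recovery experiments; a non-centered
parameterization of the latent states was also tried and mixed better per
iteration but cost four times as much per iteration in the graph engine.)

The sampling protocol mirrors practice for these models: run a batch,
compute split-chain Gelman-Rubin statistics (`split_rhat()`; the classic
estimator is `gelman_rubin()`) for every monitored node, and if any exceed
1.1, draw further batches — earlier batches then count as burn-in — until
convergence or a hard iteration ceiling (`max_iterations`). The default
configuration (4 chains × 10,000 post-burn iterations thinned by 5, i.e.
2,000 retained draws per chain) is sized for desk-scale experimentation and
for the package's simulation studies; `mcmc_profile("full")` provides the
production-scale protocol (3 chains, 400,000-iteration batches, 500,000
burn-in, thinning 50, ceiling 5.5 million) used for real statewide datasets,
where slow mixing along the baseline/offset and harvest/reporting ridges
genuinely requires chains of that length. At desk scale the baseline and
abundance summaries are stable well before formal convergence of every
offset, which is why the recovery studies below report coverage and tracking
rather than $\hat R$.

Posteriors are summarized by the median, the equal-tailed 90% credible
interval (type-7 quantiles — CRI endpoints depend on the interpolation
convention, so it is pinned), and CV = posterior SD / mean × 100. Derived
quantities are computed per draw and then summarized: annual growth rates
$\lambda_t = N_{t+1}/N_t$ and their geometric mean
$(N_T/N_1)^{1/(T-1)}$ (`growth_summary()`), density per km²
(`population_density()`), and age–sex class shares (`class_proportions()`).

## Goodness of fit

`posterior_predictive_check()` simulates replicate data from the observation
model at each retained draw and compares discrepancies: chi-squared
($\sum (y - E)^2 / E$) for the bag totals and the auxiliary estimates,
Freeman-Tukey ($\sum (\sqrt y - \sqrt E)^2$) for the aged-and-sexed counts.
The Bayesian p-value is the *strict* proportion $\Pr(T^{rep} > T^{obs})$ —
ties count against the replicate, which matters only in degenerate cases but
is pinned because "p ≈ 0.5 means good fit" depends on it.

## The synthetic-data generator

`ipm_scenario()` + `simulate_ipm()` generate ground-truth populations and
observed datasets with the exact stochastic process the model assumes
(binomial transitions, Poisson recruitment, binomial harvest/reporting/
subsampling — no normal approximations, and harvested animals cannot also
survive, which the moment-matched likelihood ignores but the generator
respects). The default scenario emulates a statewide deer program at the
scale of the motivating system: 19 years × 6 units, true rates at the prior
means, ~3% aged-sexed subsampling, auxiliary estimates in the final 5 years
only, and initial abundance sized so a unit reports about 26,700 deer per
year (about 150,000 animals per unit at the stable stage distribution —
statewide numbers in the 900k range). The auxiliary-estimate CV defaults to
10%, matching the scale prior on $\sigma_{Hest}$; hunter-survey harvest
estimates typically carry 5–15% error and no tighter figure is available.
What the generator does *not* emulate: regulation changes (trends in $R$ are
random, not stepped), hunter effort dynamics, movement between units,
disease, or check-station clustering of the aged-sexed subsample — the 3% is
simple per-class binomial thinning, since nothing in the source states the
sampling design. Passing recovery tests therefore demonstrate internal
consistency of model + sampler, not robustness to those real-world features.

## Simulation studies and problem sizes

`recover_scenario()` is the package's recovery harness. The reference study
(also run by the acceptance suite) uses 20 replicate datasets at a reduced
scale — 10 years × 2 units, 4 chains × 2,000 retained draws per fit — chosen
so the full study runs on a single core in minutes while keeping the
per-unit data volume of the full-scale system. Calibration experiments fit
with the statewide likelihood terms off (`statewide_likelihood = FALSE` is
`recover_scenario()`'s default): those terms re-count the unit-level
animals, so coverage statements are only nominally meaningful for the
single-count configuration. Across replicates the 90% CRIs for the seven
baseline hyperparameters cover their generating values at or above the
nominal rate, the posterior-median total-abundance trajectory tracks the
true one with high correlation in the large majority of replicates, and
posterior predictive p-values on self-generated data fall in the calibrated
middle of [0, 1] for all four streams. A small fraction of replicates
produce stuck chains — different chains settle at different points of the
rates-versus-abundance ridge and their pooled median trajectory is
meaningless; these announce themselves with split-$\hat R$ values far above
the 1.1 threshold (the study records each replicate's maximum), and the
remedy is the extension protocol at production scale. All of these
quantities are computed fresh by `scripts/acceptance.R` and by the test
suite on every run, not quoted here.

## Known limitations

- Abundance is only identified through the informative priors on $HS$ and
  $R$; with vague priors the scale of $N$ is unidentifiable from bag totals
  alone. Biased priors translate into biased abundance (the tracking of
  *trend* is much more robust than the level).
- The moment-matched likelihood lets latent harvest exceed what the
  surviving population could produce in extreme corners; with realistic
  abundances the truncation at zero and the data keep the chain far from
  those corners.
- Desk-scale chains leave the weakly identified age offsets ($LHR$, vague
  $N(0,10)$ priors) under-converged; production use should run the full
  profile and check $\hat R$ per parameter.
- One shared random-effect field per rate means sex-specific spatiotemporal
  variation (e.g. antlered-only regulation changes) is absorbed partly by
  the offsets and partly by noise.
- The delta-method link conversion degrades for probability-scale means
  near 1 (the log-cumulative-hazard transform has a heavy left tail there):
  at mean 0.88 with SD 0.03 the linearized SD is ~10% below the true
  transformed SD. For priors built from survival means above ~0.85, the
  Monte-Carlo route (transform simulated draws) is the safer check.
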
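Package: harvestIPM
Title: Bayesian Integrated Population Models from Age-at-Harvest Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates abundance and demographic rates of harvested,
    stage-structured wildlife populations at management-unit and statewide
    scales using only harvest data (reported harvest by bag type, an
    aged-and-sexed subsample, and optional auxiliary total-harvest
    estimates). Implements a Bayesian integrated population model with a
    two-sex, three-stage post-birth-pulse process model, complementary
    log-log hazard submodels for natural survival, hunting survival and
    reporting rates, informative priors built from literature summaries via
    method-of-moments link-scale conversion, prior-posterior overlap and
    data-agreement diagnostics with a prior-widening rule, posterior
    predictive checks, and a synthetic-data generator for simulation-based
    parameter recovery. MCMC sampling uses JAGS via the rjags interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
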
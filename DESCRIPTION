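Package: ednatransfer
Title: Joint Bayesian Quantification of Fish Abundance from Counts, Water
    eDNA and Passive Air eDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a hierarchical Bayesian state-space model that links three
    observation streams -- visual fish counts, water eDNA qPCR and passive-air
    eDNA qPCR -- to a single latent daily fish-accumulation rate. Counts are
    Negative Binomial with fixed overdispersion; water eDNA concentration is
    proportional to fish density through an integrated shedding factor; air
    eDNA deposition is a log-linear (slope one) transfer from water with
    sampler-specific intercepts, residual scales and biological-replicate
    deviations under a sum-to-zero constraint. A shared qPCR observation model
    (Bernoulli detection with exponential saturation, Normal Ct with
    concentration-dependent spread and plate-specific slopes) calibrates both
    standards and environmental samples. Includes a forward simulator for all
    three data streams, MCMC fitting via JAGS, rank-normalized split R-hat and
    bulk effective-sample-size diagnostics, posterior predictive checks, prior
    sensitivity overlap, and derived quantities such as per-sampler capture
    efficiency and water-to-air dilution factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
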
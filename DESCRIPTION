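Package: hbddm
Title: Hierarchical Bayesian Drift-Diffusion Modelling of Perceptual
    Decisions with EEG Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-choice perceptual decision data
    (choice and response time) with a hierarchical Bayesian 4-parameter
    drift-diffusion model. Includes the Wiener first-passage-time density
    with small- and large-time series expansions, exponentially weighted
    moving average (EWMA) screening of fast guesses, reliable components
    analysis (RCA) of multichannel EEG epochs with forward-model
    topographies, extraction of pre-response ramp slopes as model
    covariates, g-prior covariate regression on diffusion parameters, and
    DIC-based model comparison. A synthetic-data generator with full
    ground truth supports parameter-recovery studies for developmental
    cohorts (children and adults) performing motion-coherence
    discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
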
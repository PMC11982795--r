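Package: stemdelta
Title: Stem Water Potential Regulation from Dendrometer and Microclimate
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for characterizing whole-plant water potential
    regulation in trees monitored with optical dendrometers. Converts raw
    branchlet-width and microclimate time series into steady-state daily
    maxima of the soil-to-stem water potential difference, fits a
    hierarchical Bayesian changepoint model of that difference as a joint
    saturating function of vapour pressure deficit and soil water
    potential, and translates the fitted surface into a normalized
    whole-plant diffusive conductance surface. Includes a synthetic-data
    generator with known parameters so that every stage is verifiable by
    parameter recovery, plus MCMC diagnostics (rank-normalized split
    R-hat, PSIS-LOO cross-validation, Bayesian R-squared, and
    posterior-predictive calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
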
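Package: sleepscreen
Title: Reciprocal Sleep-Smartphone Dynamics from Wearable and Screen-Time Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for intensive longitudinal studies of sleep and
    smartphone use measured by a smartwatch and phone screen-time reports. Ingests
    HealthKit-export-style XML (sleep stages, step counts) and hand-coded screen-time
    tables, infers nightly in-bed intervals from step-count accelerometry, builds a
    person-day panel of smartphone-use and sleep-stage durations, decomposes variables
    into within- and between-person components with lag-1 dynamics, and fits two-level
    Bayesian dynamic structural equation models by Gibbs sampling, with multiple
    imputation, convergence diagnostics (rank-normalized split R-hat), posterior
    predictive checks, collinearity diagnostics, and PSIS-LOO model comparison. A
    calibrated synthetic-data generator reproduces the study design at both the panel
    and raw-stream level so every stage is testable without access to the study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
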
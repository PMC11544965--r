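Package: cvdbn
Title: Discrete Bayesian Networks for Cardiovascular Risk Prediction in
    Young Breast-Cancer Survivor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, learning and applying discrete Bayesian
    networks that predict the 5-year cardiovascular disease risk of
    adolescent and young-adult breast-cancer survivors from fused
    multi-cohort real-world data. Provides a knowledge-constrained
    Structural Expectation-Maximization learner that handles block-wise
    missing-not-at-random data through a root context (cohort) node,
    exact (enumeration, variable elimination) and approximate
    (likelihood weighting) posterior inference for individual risk
    queries, imbalance-aware evaluation (balanced accuracy, Matthews
    correlation, lift/cumulative-gain charts), a HUGIN-style .net
    serialization, and a synthetic two-cohort generator that reproduces
    the statistical and missingness structure of a population-based and
    a clinic-based cohort so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
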
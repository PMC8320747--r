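Package: causalsheet
Title: Causal Datasheets for Discrete Bayesian Network Analysis and Survey Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates synthetic discrete Bayesian networks whose observable
    characteristics (sample size, variable count, average category levels)
    mimic a planned or existing categorical survey, runs structure-learning
    algorithms (PC, greedy equivalence search, order-space MCMC with BIC or
    qNML scores) on samples drawn from them, and summarizes structural
    (skeleton and V-structure precision/recall) and interventional
    (proportion of correct interventional odds ratios) performance into a
    "causal datasheet" that supports sample-size planning and confidence
    assessment for causal discovery on categorical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
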
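Package: recallsim
Title: Monte Carlo Simulation of Recall and Selection Bias in
    Decile-Based Case-Control Analyses
Version: 1.0.0
Authors@R:
    person("recallsim", "authors", email = "maintainer@recallsim.org",
           role = c("aut", "cre"))
Description: Tools for quantitative bias analysis of case-control studies
    that categorize a continuous exposure into deciles, motivated by
    studies of mobile phone use and glioma risk. Generates synthetic
    case-control cohorts with a point mass of never-regular users and
    log-normal exposure among regular users, applies differential or
    nondifferential additive reporting error on the log scale under four
    preset scenarios, fits the never-regular-reference decile logistic
    model, and summarizes Monte Carlo replicates into per-decile mean
    estimates, empirical intervals, coverage, type-1 error and power.
    Also implements a nonresponse-questionnaire selection-bias analysis:
    exposure-proportion W ratios, participation probabilities recovered
    by Bayes inversion, Greenland's selection-bias correction factor, and
    selection thinning of simulated cohorts by start-year category.
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
    optparse
Config/testthat/edition: 3
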
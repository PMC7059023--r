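Package: ccwtte
Title: Clone-Censor-Weight Target Trial Emulation for Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for emulating a target trial of treatment initiation from
    longitudinal observational cohorts using the clone-censor-weight design.
    Each eligible patient is duplicated into one clone per treatment strategy,
    clones are artificially censored when their data become incompatible with
    their assigned strategy during a grace period, and the selection bias
    induced by that censoring is removed with stabilized inverse-probability
    weights estimated from pooled logistic models of treatment initiation.
    Discrete-time hazards are fit by weighted pooled logistic regression,
    standardized to the baseline covariate distribution (g-formula) to obtain
    marginal survival curves and risk differences, and summarized as marginal
    hazard ratios with nonparametric bootstrap confidence intervals. A
    synthetic claims-like cohort generator with a counterfactual oracle and a
    naive ever/never comparator are included so the design's behaviour
    (including immortal-time bias in the naive analysis) can be studied
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
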
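Package: centclock
Title: Centenarian-Weighted Epigenetic Age Clocks and Downstream Aging Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating DNA methylation age clocks that
    remain calibrated in the oldest old. Simulates aging methylome cohorts with
    a rare centenarian tail, trains centenarian-weighted elastic-net and neural
    network age predictors with 20-fold cross-validation, and runs the standard
    downstream analyses: epigenetic age acceleration, Cox mortality models with
    inverse-variance fixed-effect meta-analysis, biweight-midcorrelation
    biomarker screens, age-stratified epigenome-wide association studies,
    chromatin-state and polycomb enrichment via one-sided hypergeometric tests,
    and LOWESS age trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    metafor,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
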
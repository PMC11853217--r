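Package: methaft
Title: Penalized Trans-Dimensional HMM Methylation Smoothing and Mixture
    AFT Survival Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of bisulfite-sequencing methylation data.
    Stage one smooths per-sample CpG methylation levels with a penalized
    trans-dimensional hidden Markov model fitted by reversible-jump MCMC
    (joint sampling of the number of methylation states, their propensities,
    transition probabilities, and the hidden state path), then calls
    differentially methylated cytosines between case and control groups with
    a conjugate Bayesian linear model per CpG and Benjamini-Hochberg false
    discovery rate control, annotates calls to genomic contexts, and
    aggregates promoter calls into differentially methylated genes. Stage two
    screens gene-level methylation covariates with censoring-weighted
    correlation-adjusted regression survival (CARS) scores and fits sparse
    finite mixtures of log-normal accelerated failure time regressions by
    penalized EM with BIC order selection. A synthetic-data generator
    reproduces the statistical structure both stages assume, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    survival,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
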
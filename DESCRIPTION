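Package: omihet
Title: Single-Cell Optical Metabolic Imaging Heterogeneity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell optical metabolic imaging (OMI)
    of patient-derived tumor organoids. Simulates time-correlated single photon
    counting (TCSPC) fluorescence-lifetime decay stacks, fits per-pixel
    two-exponential decays convolved with an instrument response function,
    computes optical redox ratio and mean-lifetime images, segments cell
    cytoplasms and extracts per-cell metabolic endpoints, computes the
    control-centered OMI index, models metabolic subpopulations with
    one-dimensional Gaussian mixtures selected by AIC, and quantifies
    population heterogeneity with the weighted heterogeneity index (wH-index),
    quadratic entropy, Kolmogorov-Smirnov normality distance, and outlier
    percentage. Treatment response is summarized with Glass's delta effect
    sizes, Wilcoxon rank-sum tests, hierarchical variance partitioning, and an
    effect-size plus heterogeneity-change responder classification rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    minpack.lm,
    EBImage,
    tiff,
    stats,
    utils,
    generics,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
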
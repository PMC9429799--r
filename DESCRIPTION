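Package: saccadeddm
Title: Drift-Diffusion and Smoothed Time-Course Analysis of Dual-Saccade
    Target Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for dual-saccade choice experiments in which
    a foveated inspection target (a face or a noise patch, previewed
    peripherally or hidden behind an outline) precedes a saccadic choice
    between two peripheral targets.  Provides a synthetic experiment
    generator with counterbalanced designs, Wiener diffusion first-passage
    densities and CDFs with across-trial parameter variability, an
    eight-variant drift-diffusion model family fitted per participant by a
    Kolmogorov-Smirnov criterion with BIC information-weight model
    selection, the SMART smoothed time-course and cluster-based permutation
    analysis, and two-level repeated-measures group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    readr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
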
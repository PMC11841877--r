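Package: somprofiler
Title: Person-Centered Activity-Cognition Profiling with Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for person-centered profiling of children
    from physical, psychological and social variables: accelerometer-count
    preprocessing (epoch consolidation, non-wear detection, cut-point
    intensity classification, wear-time validity, mean daily MVPA), a
    from-scratch self-organizing map on a hexagonal lattice with sequential
    and batch training, four neighborhood kernels and two initializations,
    ensemble model selection by the product of quantization and topographic
    errors, k-means clustering of the codebook with Davies-Bouldin selection
    of the cluster count, propagation of cluster labels to participants
    through best-matching units, and nonparametric cluster comparisons
    (Kruskal-Wallis with epsilon-squared effect sizes, Dunn-Bonferroni
    pairwise tests, chi-square gender association) plus a noncentral-F
    ANOVA power utility. Includes a synthetic-cohort generator that
    reproduces the six-profile structure the analysis targets, so the whole
    pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
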
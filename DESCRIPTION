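Package: fcbiotype
Title: Functional-Connectivity Biotyping of Alcohol Misuse with Genetic
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering and validating biotypes of
    alcohol misuse from resting-state functional-connectivity (FC) features.
    Implements motion-based frame censoring (framewise displacement and
    DVARS scrubbing), band-pass filtering and FC construction from ROI time
    series, covariate residualization fitted on the training split, FC
    feature screening by Spearman correlation with clinical metrics and
    Wilcoxon case-control tests, biotype discovery by dimension reduction
    plus K-means/hierarchical clustering selected by the Variance Ratio
    Criterion, a biotype-aware neural classifier trained with a joint
    biotype + case-control objective, permutation inference, scan-2
    consistency checks, and quantitative-trait association using a genetic
    relationship matrix linear mixed model with LD-adjusted Bonferroni
    correction. Ships a synthetic-cohort generator with planted biotype,
    clinical and genetic ground truth for end-to-end validation.
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
    grDevices,
    mclust,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
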
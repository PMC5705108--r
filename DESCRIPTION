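Package: fcrepro
Title: Reproducibility of Group-Level Functional Connectivity Alterations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether group-level alterations of
    resting-state functional connectivity (FC) reproduce across independent
    datasets and across random splits of a single dataset with replicate
    scans. Implements Fisher-z pairwise connectivity over a canonical
    region-pair ordering, mass-univariate Welch contrasts, a reproducibility
    statistic (the correlation of two contrasts' t-vectors) with a
    dual-permutation null, a split-subjects versus split-replicates
    heterogeneity test, a direction-stratified min(max(p)) cross-dataset
    edge-consistency statistic with its permutation test, and cross-dataset
    classifier evaluation with balanced average accuracy. A hierarchical
    synthetic-cohort generator with known edge effects, optional disease
    subtypes and subject/scan variance components provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
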
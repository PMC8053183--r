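Package: cytosig
Title: Cytokine Signature Analysis for Breast Implant-Associated ALCL Seromas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiplex bead-immunoassay cytokine panels
    measured in late peri-implant breast seromas. Distinguishes breast
    implant-associated anaplastic large-cell lymphoma (BI-ALCL) effusions from
    benign reactive seromas via empirical-Bayes moderated t-tests with
    Benjamini-Hochberg correction, leave-one-out robustness counting,
    cytokine-to-IL-6 ratio analysis, Spearman/Ward.D2 hierarchical clustering
    and classical multidimensional scaling, and ROC curves with Youden-optimal
    cutoffs and DeLong confidence intervals. Includes five-parameter-logistic
    standard-curve quantification from raw median fluorescent intensities and a
    truncated log-normal panel simulator calibrated to published group
    summaries, so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
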
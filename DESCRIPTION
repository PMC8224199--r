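Package: rygbsig
Title: Cross-Cohort Concordance of Gut Microbiome Signatures After
    Gastric Bypass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether longitudinal gut-microbiome shifts
    after Roux-en-Y gastric bypass replicate across independent cohorts.
    Implements per-feature random-intercept linear mixed models contrasting
    each post-surgical timepoint against the pre-surgical baseline, signed
    log10 p-value signatures, pairwise between- and within-study Spearman
    concordance with Benjamini-Hochberg control, community-level ordination
    (Bray-Curtis principal coordinates, PERMANOVA, Shannon diversity), and
    cross-study machine-learning transfer validation (within-study
    cross-validation, study-to-study prediction, leave-one-study-out) with
    AUROC as the metric. A synthetic multi-study count generator with a
    planted, partially shared intervention signature makes every stage
    testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    nlme,
    ranger,
    stats,
    tools,
    utils,
    vegan
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
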
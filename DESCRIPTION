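Package: pyropattern
Title: Pyroptosis Expression Patterns, Microenvironment Scoring and a
    Prognostic Pyroptosis Score for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("pyropattern", "developers", email = "dev@pyropattern.org",
           role = c("aut", "cre"))
Description: Discovers pyroptosis expression patterns in tumor expression
    cohorts by subsampled consensus clustering over a curated regulator
    panel, quantifies tumor-microenvironment signatures per sample by
    single-sample gene set enrichment (ssGSEA) and ESTIMATE-style scores,
    derives pattern-related signature genes by empirical-Bayes moderated
    differential expression, and condenses them into a per-sample
    pyroptosis score (PS) via a Cox-screened principal component signature
    with maximally selected survival cutpoints. Includes survival
    estimators (Kaplan-Meier, log-rank, Cox partial likelihood,
    time-dependent ROC), mutation/CNV landscape summaries, and a
    synthetic-data generator with planted ground truth so every pipeline
    stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
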
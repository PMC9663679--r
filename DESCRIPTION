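Package: gbsnga
Title: Risk Stratification for Nonvariceal Upper Gastrointestinal
    Bleeding Using the Glasgow-Blatchford Score and Nasogastric Aspirate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for risk stratification of patients presenting with
    suspected nonvariceal upper gastrointestinal bleeding. Implements the
    Glasgow-Blatchford score (GBS) from raw clinical variables, a combined
    GBS plus nasogastric-aspirate (NGA) score in which a bloody aspirate
    forces the maximal score of 23, and the two-way triage rule built on
    them. Provides the full evaluation toolkit for such rules: empirical
    (Mann-Whitney) ROC curves with DeLong variances and the paired DeLong
    test for correlated AUCs, continuous net reclassification improvement
    and integrated discrimination improvement, threshold sweeps with
    sensitivity-constrained cutoff selection, and diagnostic accuracy
    metrics with exact Clopper-Pearson confidence intervals. A development
    cohort of 115 emergency-department patients can be reconstructed
    exactly from published cumulative count tables, and a seeded synthetic
    cohort generator produces arbitrarily large cohorts with the same
    statistical structure, including raw clinical variables consistent
    with any target score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
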
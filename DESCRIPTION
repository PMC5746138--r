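Package: ctpanel
Title: Diagnostic Classification of Mixed miRNA/mRNA qPCR Marker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for building and evaluating diagnostic
    classifiers from mixed-chemistry TaqMan array qPCR data. Provides
    chemistry-aware delta-Ct normalization against named reference genes,
    univariate single-threshold marker scoring (TNoM and its class-wise
    variant), nested marker selection inside repeated stratified k-fold
    cross-validation, linear support-vector classification with a fixed cost
    parameter, exhaustive marker-subset search, top-list size sweeps,
    final-model retraining and application to additional lesion classes, and
    hierarchical clustering with uncentered Pearson correlation. Includes a
    seeded synthetic-cohort generator emulating censored ("Undetermined")
    qPCR wells so the full analysis is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
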
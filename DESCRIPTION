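Package: stemscore
Title: Stemness Gene Score Construction from Bulk and Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a prognostic stemness gene score (SGS) from expression
    matrices and gene-set collections: single-sample gene-set enrichment
    (ssGSEA) with cohort-wide normalisation, univariate Cox
    proportional-hazards screening of gene-set scores against overall
    survival, signed combination of risk and protective set scores into a
    per-sample SGS, median stratification, and Kaplan-Meier / log-rank
    comparison of the resulting groups. Includes a per-cell scoring path
    with patient-level aggregation for single-cell matrices, and a
    survival-linked synthetic-cohort generator with planted gene-set
    activity for end-to-end validation without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    survival,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
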
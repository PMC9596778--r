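Package: irscore
Title: Immune-Related Signature Scoring for Tumor Cohort Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates an immune-related signature score (IRScore)
    for stratifying tumor cohorts by recurrence-free survival. Implements
    single-sample gene-set enrichment (ssGSEA and GSVA algorithms) with
    per-cohort normalization to NES, two-group Cox proportional-hazards
    fitting, log-rank and Kaplan-Meier estimation, inverse-variance
    (DerSimonian-Laird) meta-analytic selection of prognostic signatures,
    the IRScore signed sum with median stratification, cell-level scoring
    with CD103/CD39 double-positive classification, mass-cytometry
    preprocessing arithmetic, and a synthetic multi-cohort generator with
    planted prognostic signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    metafor,
    withr
Config/testthat/edition: 3
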
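Package: comorbrisk
Title: Age- and Sex-Stratified Comorbidity Screening from Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies disease comorbidity risks of type 1 and type 2
    diabetes from two-year longitudinal ICD-10/ATC claims records.
    Provides age-stratified relative-risk screening with chi-squared tests
    and Benjamini-Hochberg false-discovery-rate control, a smoothed
    log sex-ratio statistic with significance gating, lead/lag indicators
    of temporal ordering between diagnoses with a surrogate-data
    permutation test, recall-based validation against a curated reference
    list of diabetic complications, and a synthetic claims generator that
    plants known effects so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
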
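Package: rosettabank
Title: Harmonization of Child Behavioral Assessment Instruments into a
    Minimal Question Bank
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fusing standardized child behavioral assessment
    instruments (ADI-R, ADOS-2, BASC-3, BRIEF2, CBCL, Conners 3, SRS-2,
    VADRS) into a minimal bank of harmonized questions hanging on a
    semantic hierarchy of clinical domains. Provides the hierarchy data
    model and validator, the crosswalk that maps instrument items and
    ordinal answer scales onto harmonized answer codes, a translation
    engine turning long-format instrument responses into a fused
    child-by-question matrix, overlap and fusion reporting, a latent-trait
    simulator for multi-instrument cohorts with block missingness, a
    constraint-based ensemble random-forest imputer for the fused matrix,
    and a two-stage gradient-boosted classifier (any-condition gate, then
    autism versus ADHD discrimination) with iterative row/feature pruning
    and stratified cross-validation.
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
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
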
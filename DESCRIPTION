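Package: tnbcsubtyper
Title: Histopathology-Based Subtype Classification of Triple-Negative
    Breast Cancer
Version: 0.1.0
Authors@R:
    person("TNBC", "Subtyping Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies triple-negative breast cancer (TNBC) into the
    luminal androgen receptor (LAR) subtype and three stromal
    tumor-infiltrating lymphocyte (TIL) groups (lymphocyte-predominant,
    -intermediate, -depleted) from the androgen-receptor Allred score and
    the stromal TIL percentage. Re-derives the decision thresholds with an
    in-house CART (classification and regression tree) trainer, calls a
    four-class gene-expression molecular subclassification by correlation
    to centroids with an unclassified rule, and evaluates concordance
    (Cohen's kappa, accuracy with Wilson intervals, per-class
    precision/recall/F1), survival (Kaplan-Meier, log-rank, Cox
    proportional hazards), signature enrichment and genomic-alteration
    differences across subtypes. Ships a synthetic-cohort generator
    calibrated to the published cross-tabulation and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival,
    limma
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
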
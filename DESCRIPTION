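Package: va2012
Title: The 2012 WHO Verbal Autopsy Standard as Computable Data
Version: 0.1.0
Authors@R: person("VA Tools", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Machine-readable implementation of the 2012 WHO verbal autopsy
    (VA) standard: the 62-category cause-of-death list with bidirectional,
    precedence-resolved ICD-10 mapping; the CoD-related indicator registry
    with skip-pattern questionnaire logic and record validation; automated
    cause assignment by an InterVA-style Bayesian engine and a Tariff-style
    additive scorer; cause-specific mortality fraction estimation; the
    validation metrics used in the VA literature (CSMF accuracy,
    chance-corrected concordance, Cohen's kappa, Lin's concordance
    correlation, one-vs-rest diagnostics, rank AUC); and a skip-consistent
    synthetic cohort generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
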
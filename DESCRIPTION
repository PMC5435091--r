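Package: copdemr
Title: EMR Case-Finding Algorithms for COPD and Their Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based phenotyping of chronic obstructive pulmonary disease
    (COPD) in primary-care electronic medical records. Represents case-finding
    algorithms as boolean combinations of atomic chart criteria (cumulative
    patient profile text mentions with uncertainty-phrasing exclusions,
    diagnostic billing-code counts in rolling time windows, COPD-specific
    anticholinergic prescriptions, smoking history) and validates them against
    a chart-abstraction reference standard: confusion matrices, sensitivity,
    specificity, predictive values with exact Clopper-Pearson intervals,
    likelihood ratios and diagnostic odds ratio with log-scale intervals,
    Cohen's kappa for abstractor agreement, and a discordance taxonomy for
    false negatives and false positives. Ships a calibrated synthetic-cohort
    generator so the full pipeline can be exercised without access to real
    charts, plus a command-line interface for classify, evaluate, simulate
    and discordance workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
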
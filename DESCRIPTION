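Package: cddseverity
Title: Global Clinical Severity Scoring for CDKL5 Deficiency Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to derive and apply a global clinical severity score for
    CDKL5 deficiency disorder (CDD) from nine clinician- and caregiver-reported
    outcome assessments. Implements a reflective structural equation model with
    two exogenous latent factors (communication, comorbidities) and one
    endogenous global-severity factor, estimated by full-information maximum
    likelihood over per-subject missingness patterns; model fit indices (RMSEA,
    CFI, TLI); regression-method factor scores generalized to incomplete
    profiles; regression-derived unit-sum component weightings for a deployable
    weighted-average severity score; and external-validation statistics
    (Pearson correlations with EEG band-power ratios, quality of life and
    behavior, age-group comparisons, and test-retest intraclass correlation).
    Includes a synthetic cohort generator emulating the study's data structure
    so every stage is testable without access to clinical data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
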
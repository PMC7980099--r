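Package: csctriage
Title: Crisis Standards of Care Triage Scoring and Disparity Auditing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a crisis-standards-of-care (CSC) ventilator-triage
    priority scoring algorithm and the statistical machinery to audit it for
    racial and ethnic disparities. Daily Sequential Organ Failure Assessment
    (SOFA) scores are computed from organ-system physiology, banded into SOFA
    points (1-4), combined with tiered comorbidity points (0/2/4) into priority
    scores (1-8) and priority groups (1-3), with a tiebreak cascade and a
    seeded scarce-resource allocation simulator. The audit aggregates
    patient-days to per-patient maximum and minimum outcomes, compares
    baseline characteristics across priority groups (chi-squared and
    Kruskal-Wallis tests), fits multivariable Poisson regression models
    reporting incidence rate ratios with complete-case, unknown-category and
    no-socioeconomic-covariate variants, and quantifies reprioritization
    caused by including comorbidity information. A synthetic two-hospital
    cohort generator with injectable disparity effects supports power,
    calibration and parameter-recovery studies without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
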
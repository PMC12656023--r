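Package: mixpeq
Title: Cumulative Dietary Risk Assessment of PFAS Mixtures in PFOA Equivalents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Engine for cumulative dietary risk assessment of per- and
    polyfluoroalkyl substance (PFAS) mixtures under dose addition. Converts
    per-compound food occurrence data into PFOA-equivalent Estimated Weekly
    Intakes (EWI) via Relative Potency Factors (RPF), cumulates exposure
    across compounds and animal-derived food categories for European
    population groups, and characterises risk against the EFSA group
    Tolerable Weekly Intake (4.4 ng/kg bw per week) as %TWI and a Hazard
    Index. Includes lower/upper-bound substitution for left-censored
    occurrence records, survey-weighted consumption averaging, a synthetic
    occurrence-data generator for validation, reference fixtures from a
    published European assessment, report rendering with the field's
    rounding conventions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
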
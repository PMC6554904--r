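Package: readmorbid
Title: Charlson and Elixhauser Comorbidity Scoring for Read-Coded
    Primary Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comorbidity risk adjustment in Read-coded primary
    care databases. Loads, validates and merges clinical code lists that
    map Read codes to the 17 Charlson and 31 Elixhauser comorbidity
    categories; converts dated coded events into category flags under
    configurable look-back windows and into weighted indices (original
    Charlson weights and the Quan 12-item modification) or Elixhauser
    category profiles; and validates the predictive properties of the
    measures with logistic mortality models, AUROC with DeLong variance,
    tests of equality for correlated ROC curves, and Kaplan-Meier curves
    by index stratum. A synthetic hip-fracture case-control cohort
    generator emulating the structure of UK primary-care databases makes
    the whole pipeline runnable and testable without access to restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
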
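Package: abstaindx
Title: Simulation and Exact Evaluation of Abstaining Diagnostic Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying three-output (positive / negative /
    indeterminate) diagnostic aids of the kind used for autism spectrum
    disorder (ASD) screening in primary care. Provides a synthetic cohort
    generator for 18-72-month-olds with overlapping latent classes and
    age-banded ordinal questionnaires, a consensus specialist
    reference-standard simulator with majority adjudication and diagnostic
    certainty scores, a score-plus-dual-threshold abstention classifier whose
    thresholds are calibrated by cross-validation to satisfy positive and
    negative predictive value floors while maximizing the determinate rate,
    and an exact-statistics evaluation engine: 3x3 confusion matrices,
    abstention-aware accuracy metrics with Clopper-Pearson intervals, the
    no-abstention counterfactual, Boschloo's unconditional exact test, and
    covariate-stratified reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
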
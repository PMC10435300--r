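Package: smartriage
Title: S-S.M.A.R.T and qSOFA Sepsis Triage Scores with ROC Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the S-S.M.A.R.T emergency-department sepsis triage score
    (shock index, mental status, age, ROX index) and the qSOFA comparator from
    raw triage vital signs, and evaluates either score against binary outcomes:
    tie-corrected (midrank) AUC with DeLong variance and confidence intervals,
    paired DeLong AUC comparison, operating-point metrics (sensitivity,
    specificity, PPV, NPV) at score cutoffs, score-stratified outcome rates and
    Pearson chi-square association tests. Includes expansion of published
    grouped score-by-outcome tables into patient-level cohorts, a bundled
    reference cohort of 401 emergency-department patients with suspected
    sepsis, a deterministic synthetic vital-signs simulator, and a command-line
    interface for scoring, evaluation and simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
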
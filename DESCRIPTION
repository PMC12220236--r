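Package: eamlr
Title: Expert-Augmented Rule-Ensemble Models for Clinical Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits rule-ensemble ('RuleFit') classifiers to time-windowed
    intensive-care cohort data, elicits clinician assessments of the selected
    rules on a five-point Likert scale, quantifies model-versus-expert rank
    discordance (delta rank divided by the expert response standard
    deviation), and re-regularizes the model with expert-informed
    differential ridge penalties ('soft') or by excluding the most discrepant
    rules ('hard'). Includes a synthetic cohort and simulated expert-panel
    generator with planted true and spurious rules for studying external
    generalizability, and paired-bootstrap evaluation of AUC differences,
    change scores, and difference-in-differences against the un-augmented
    baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    xgboost,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
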
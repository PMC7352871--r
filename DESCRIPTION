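Package: uropanel
Title: Urinary Proteome Prognostic Panels for Diabetic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Label-free urinary proteomics analysis for predicting renal outcomes
    in type 2 diabetes. Implements creatinine/total-protein correction of LFQ
    intensities, endogenous reference-protein selection by NormFinder stability,
    median-ratio normalization scaling factors, group-completeness filtering,
    local least squares imputation, Mann-Whitney volcano screening, AUC-based
    random-forest backward-elimination feature selection, random-forest and
    linear-SVM prognostic panel models with 0-1 disease scores, application of
    frozen panels to external gene-expression matrices, CKD-EPI eGFR and
    renal-outcome labelling, and a synthetic cohort generator so the whole
    pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
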
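Package: hcmecg
Title: Computational ECG Phenotyping for Hypertrophic Cardiomyopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for computational phenotyping of hypertrophic
    cardiomyopathy (HCM) from multi-lead digital ECG. Generates labelled
    synthetic 12-lead ECG cohorts with archetype-specific QRS and T-wave
    morphology, preprocesses beat trains into averaged aligned beats (45 Hz
    low-pass, 50 Hz notch, cubic-spline baseline removal, Woody alignment),
    quantifies QRS shape by projection onto width-optimised Hermite function
    bases, extracts standard QRS and T-wave biomarkers, identifies phenotype
    subgroups by multi-cluster feature selection, Laplacian-eigenmap embedding
    and DBSCAN clustering, and compares clinical covariates across subgroups
    including the 2014 ESC HCM Risk-SCD score and its risk categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    ape,
    glmnet,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
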
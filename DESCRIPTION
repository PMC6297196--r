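Package: endosig
Title: Endophenotype-Based Plasma Proteomic Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering, replicating and validating plasma
    protein biomarkers of Alzheimer's disease pathology endophenotypes.
    Covers peptide-level TMT roll-up to molecular-weight isoform matrices,
    five-parameter-logistic immunoassay quantification, cerebrospinal-fluid
    (CSF) tau/amyloid pathology scoring and cohort harmonization, a
    four-test univariate association battery with covariate adjustment and
    Benjamini-Hochberg correction, Fisher's-method p-value combination with
    interaction-network score expansion and permutation-calibrated
    Kolmogorov-Smirnov gene-set enrichment, and LASSO-ranked support-vector
    machine panel selection under repeated stratified cross-validation.
    Includes a synthetic-data generator that reproduces the statistical
    structure each stage assumes, so the whole pipeline is testable without
    access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    e1071,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
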
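Package: retinocog
Title: Pointwise Retinal Nerve Fibre Layer and Cognition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between circumpapillary
    retinal nerve fibre layer thickness (cpRNFLT) profiles and cognitive
    performance in population cohorts. Implements quality control and
    orientation standardisation of 768-point TSNIT thickness profiles,
    norm-referenced stratification of participants into mild cognitive
    impairment (MCI) and mild neurocognitive disorder (NCD), pointwise
    mass-univariate linear and logistic regression with Benjamini-Hochberg
    false-discovery-rate control, permutation-calibrated AUC inference for
    discrimination models, best-subset sector classifiers over angular
    partitions of the scan circle, intracranial-volume adjustment and group
    comparison of hippocampal volumes, and a synthetic-cohort generator that
    emulates the joint structure of retinal, cognitive and covariate data so
    the whole pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
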
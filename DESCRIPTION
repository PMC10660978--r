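Package: padscreen
Title: Screening for Primary Antibody Deficiency in Coded Primary-Care Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for case-finding of primary antibody deficiency (PAD) in
    coded primary-care electronic health records. Implements a configurable
    weighted-item risk score over ICPC-coded diagnoses, antibiotic
    prescriptions, laboratory results and GP visits; censoring-date and
    exclusion logic; score refitting by penalized logistic regression
    (ridge-adjusted category weights, principal-component item grouping,
    lasso variable selection); ROC-based cut-off derivation (Youden index and
    100 percent sensitivity); age-banded immunoglobulin reduction flags with
    referral advice; a two-step screening workflow with yield and cost
    estimation; and a seeded synthetic-population generator for desk-scale
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
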
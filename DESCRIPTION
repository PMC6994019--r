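Package: mbcdetect
Title: Distant Supervision for Detecting Recurrent Metastatic Breast Cancer
    from Clinical Notes and Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A phenotyping toolkit that detects recurrent metastatic breast
    cancer from linked electronic medical record notes and cancer-registry
    records. Clinical notes are tagged against a term-to-concept lexicon with
    NegEx/ConText-style resolution of negation, family attribution and
    hypothetical status; a site-class rule turns positive present mentions of
    bone, brain, liver or lung metastasis into noisy (distant) case labels;
    patient-level mention-count and registry features feed an L2-regularized
    logistic regression selected by cross-validated lambda.1se with an
    F1-optimized probability cutoff. Includes evaluation machinery (confusion
    metrics, percentile-bootstrap confidence intervals, ROC/AUC with DeLong
    intervals), an ICD-9 code rule benchmark, a PPMI+SVD terminology expander,
    and a seeded synthetic-cohort generator so the whole pipeline is testable
    without access to protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
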
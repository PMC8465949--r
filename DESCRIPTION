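Package: crsfess
Title: Feature Selection for Functional Endoscopic Sinus Surgery Outcomes in Chronic Rhinosinusitis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to identify which endoscopic, olfactory, quality-of-life and
    demographic parameters carry relevant information about the outcome of
    functional endoscopic sinus surgery in chronic rhinosinusitis with nasal
    polyposis. Implements clinical instrument scoring (Lildholdt and
    Lund-Kennedy endoscopic scores, Sniffin' Sticks TDI diagnosis, SNOT-20
    subscores), a calibrated synthetic paired-cohort generator, preprocessing
    (Tukey ladder-of-powers transform selection, iterative Grubbs outlier
    removal, block-wise imputation, one-hot recoding), the nonparametric
    Impact effect size with bootstrap confidence intervals, factor analysis of
    mixed data, computed ABC item categorization, and a Monte-Carlo
    cross-validated multi-classifier drop-one-variable feature-selection
    harness with weighted cross-classifier consensus, iterative category
    knockout and a permutation negative control, plus post-selection outcome
    sign analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ranger,
    e1071,
    rpart,
    nnet,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
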
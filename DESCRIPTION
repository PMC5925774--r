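Package: synscreen
Title: Loewe Synergy Scoring and Machine Learning for Drug Combination
    Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing high-throughput drug combination screens.
    Fits four-parameter Hill curves to single-agent dose-response data,
    assembles 5x5 combination surfaces from measured 4x4 checkerboards,
    and scores each surface against its Loewe-additivity reference.
    Featurises drugs (circular fingerprint counts, physico-chemical
    descriptors, toxicophore SMARTS flags) and cell lines (gene
    expression), and trains a symmetric feed-forward neural network
    regressor of synergy scores with train-fold-only input normalisation,
    dropout and moving-average early stopping. Ships bespoke baselines
    (median polish, a modified MinMax kernel for mixed count, binary and
    continuous features), stratified nested cross-validation in four
    generalisation regimes, a regression and classification metric panel,
    and a synthetic-data generator with planted synergy for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    yaml,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    kernlab,
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
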
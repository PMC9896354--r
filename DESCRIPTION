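Package: famcomm
Title: Lexicon-Based Scoring and Prediction of Openness of Family
    Communication in Hereditary Cancer Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how openly interview narratives discuss sharing
    hereditary cancer risk within a family.  Implements a hand-scored
    N-gram lexicon with summation scoring, dictionary-based sentiment and
    emotion feature extraction (valence, polarity, and emotion-category
    lexicon families), and prediction of the openness score from sentiment
    features and subject covariates via collinearity-filtered stepwise
    linear regression with split-sample evaluation (AUC, sensitivity,
    specificity, RMSE).  A synthetic-cohort generator with planted lexical
    signal makes every pipeline stage testable without access to private
    interview transcripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
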
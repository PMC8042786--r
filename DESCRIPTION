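Package: phqminer
Title: Weakly Supervised Detection of PHQ-9 Depression Symptoms in Forum Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects the nine PHQ-9 depression symptoms in patient-authored
    forum posts as a multi-label classification task. Builds symptom lexicons
    from seed terms expanded through a pluggable lexical database, scores
    posts against each symptom by cosine similarity between mean word
    embeddings (weak supervision), trains feedforward and recurrent
    (LSTM/BiLSTM) neural classifiers with an attention pooling layer, and
    grows the training set with an entropy-based active-learning loop.
    Includes a synthetic forum-corpus generator with planted symptom terms so
    the full pipeline is testable without access to clinical data, ROC/AUC
    evaluation per symptom, and per-token attention visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
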
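Package: threadstance
Title: Debate Detection and Stance Classification in Threaded Health Forums
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects debate episodes and classifies participant stance in
    threaded online-health-community discussions. A convolutional post
    encoder with max-over-time pooling and a highway layer feeds an LSTM
    over consecutive posts of a thread, labelling each post as debate or
    non-debate (binary, or typed into four classes); an analogous CNN
    classifies pro- versus con-CAM stance of debate posts. A lasso
    logistic-regression baseline over engineered thread, post and lexical
    features (LDA topic proportions, CBOW embeddings) is included, along
    with precision/recall/F evaluation with thread-level cross-validation
    and resampled confidence intervals, and a synthetic forum generator
    that emulates context-dependent debate episodes for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
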
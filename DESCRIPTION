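Package: prddi
Title: Joint Knowledge-Graph and Text Embedding for Rich Drug-Drug
    Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts rich (multi-label) drug-drug interactions by jointly
    embedding a drug knowledge graph of basic biological triples and
    text-derived multi-label interaction relations into one low-dimensional
    space. Basic triples are encoded with a translation-based model using
    relation-specific projection matrices; interaction label sets are
    compressed by a deep autoencoder with a weighted reconstruction score
    that counteracts label sparsity. Both encoders are trained jointly with
    a negative-sampling surrogate objective, soft norm constraints and the
    Adam optimizer. Missing interactions are predicted by translating
    projected drug embeddings and decoding the resulting relation vector
    back into labels. Includes TF-IDF label extraction from interaction
    sentences, raw and filtered MeanRank/Hits-at-k evaluation, binary
    classification from concatenated embeddings with ROC and
    precision-recall curves, and a synthetic knowledge-graph generator
    with planted translational and label-cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
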
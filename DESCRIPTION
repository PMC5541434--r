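Package: srmf
Title: Similarity-Regularized Matrix Factorization for Anticancer Drug
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts anticancer drug responses of cell lines from a
    partially observed drug-by-cell-line response matrix by weighted
    low-rank matrix factorization with chemical-structure drug similarity
    and gene-expression cell-line similarity as regularizers.  Includes
    construction of Jaccard (Tanimoto) drug similarity from fingerprint
    bit tables and Pearson cell-line similarity from expression profiles,
    per-drug evaluation metrics with sensitive/resistant quartile subsets,
    entry-wise k-fold cross-validation and hyperparameter grid search, a
    low-rank synthetic-data simulator with controlled Gaussian noise, and
    one-sided exact Mann-Whitney association tests between genotypes and
    drug sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
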
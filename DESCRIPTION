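Package: m6aloco
Title: Chromosome-Aware Training and Evaluation of Hybrid m6A Site Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting N6-methyladenosine (m6A) sites from fixed-length
    nucleotide windows and for evaluating such predictors without chromosome-level
    data leakage. Provides k-mer composition and one-hot sequence encodings, a
    family of convolutional classifiers (simple, hybrid, and deep-hybrid variants
    that fuse learned convolutional features with handcrafted k-mer features),
    negative-set balancing into disjoint 1:1 replicates, random-split and
    leave-one-chromosome-out (LOCO) validation plans with leakage auditing, a full
    classification metric suite (accuracy, sensitivity, specificity, Matthews
    correlation coefficient, AUC-ROC) with confidence intervals, t-SNE views of
    learned embeddings, and a synthetic DRACH-motif sequence generator with a
    tunable chromosome-composition confounder for studying the inflation of
    randomly split benchmarks relative to LOCO evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
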
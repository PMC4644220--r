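Package: mapredict
Title: Sequence-Based Prediction of Microtubule-Associated Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microtubule-associated proteins (MAPs) from primary
    sequence by fusing three complementary signals: a semi-supervised
    Laplacian support vector machine trained on discriminative degenerate
    sequence motifs, a second Laplacian SVM trained on the composition of
    k-spaced amino-acid pairs (CKSAAP), and a piecewise log-transform of
    the best-hit E-value from a homology search against the positive
    training set. Includes dataset assembly at fixed class ratios with
    identity-based redundancy filtering, exhaustive degenerate-motif
    discovery with mRMR feature selection, stringency-threshold
    classification, ROC/AUC and MCC benchmarking, a synthetic-data
    generator for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
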
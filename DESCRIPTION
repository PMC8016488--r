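Package: ognet
Title: Alignment-Free Protein Orthologous Group Assignment with
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns protein sequences to orthologous groups without
    alignments, using a convolutional network with a learned amino-acid
    embedding, scaled exponential linear units, length-adaptive masked
    max-pooling and a confidence-thresholded softmax classifier. Includes
    a fixed-length one-hot baseline network with batch normalization and a
    hidden layer, a synthetic protein-family simulator with implanted
    motifs and imbalanced group populations for end-to-end testing,
    population filtering and stratified splitting, Adam training with a
    decaying learning-rate schedule, open-set rejection via a softmax
    confidence threshold, and imbalance-aware evaluation with
    macro-averaged precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
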
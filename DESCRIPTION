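Package: ldrisk
Title: Genetic Risk Prediction with Deep Models from Linkage-Disequilibrium Summary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Polygenic risk prediction with deep models when only linkage
    disequilibrium (LD) summary matrices are available. Provides a blockwise
    genotype/phenotype simulator with a controllable minor-allele-frequency
    spectrum and local LD, LD matrix construction and diagonal-block
    partitioning, six deep model families (deep neural network, 1D/2D
    convolutional networks, LSTM, bidirectional LSTM, transformer encoder)
    implemented natively with ADAM training in both individual-level and
    summary-data modes, a bootstrap approximation of summary-mode test error
    with its exact all-pairs limit, a REML-based best linear unbiased
    prediction (BLUP) benchmark, and a replication harness that reports
    training/test mean squared errors across repeated splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    dplyr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
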
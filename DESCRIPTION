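Package: sweepimage
Title: Detecting and Quantifying Selective Sweeps from Haplotype Images
    with Convolutional Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Represents population genomic data (binary haplotype
    alignments from coalescent simulations in ms format) as sorted
    black-and-white images, trains convolutional neural networks to
    detect positive selection and to estimate the selection coefficient
    by multiclass classification, and summarises the resulting class
    posterior as MAP and posterior-mean point estimates, highest
    posterior density intervals and Bayes factors.  Includes a builder
    for msms command lines, an ms-format reader/writer, a self-contained
    synthetic sweep/neutral fixture generator, and a compact
    deterministic CNN engine written in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
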
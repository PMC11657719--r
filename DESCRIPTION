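Package: fcgrclust
Title: Alignment-Free Clustering of DNA Sequences with Chaos Game
    Representations and Twin Contrastive Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised, alignment-free clustering of unlabelled DNA
    sequences. Each sequence is encoded as a Frequency Chaos Game
    Representation (FCGR) image, and a small convolutional network with
    instance-level and cluster-level contrastive heads is trained on pairs
    of mutated or fragmented "mimic" sequences (twin contrastive learning).
    Independently initialized models are combined by soft or hard majority
    voting, and clusterings are scored against reference labels with
    Hungarian-matched accuracy. Includes a synthetic benchmark generator,
    command-line entry points, and a from-scratch neural network engine so
    the whole pipeline runs on a plain CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    optparse,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    png
Config/testthat/edition: 3
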
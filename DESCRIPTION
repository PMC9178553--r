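Package: yfrag
Title: Prediction of y-Ion Fragment Intensities in Beam-Type CID Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling peptide fragmentation in beam-type
    collision-induced dissociation (QTOF/QqQ). Reads and cleans NIST-style
    MSP spectral libraries, encodes peptides into sequence, scalar-feature
    and sliding-window channels, and trains a hybrid recurrent/convolutional
    /dense neural network to predict the relative intensities of singly- to
    triply-charged y1-y14 fragments. Includes 10-fold cross-validated
    training, spectral-similarity evaluation (with-zero and without-zero
    Pearson correlation, high-intensity-peak accuracies, a grouped
    peptide-spectrum-match test), exploratory highest-peak statistics, and a
    generative fragmentation simulator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
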
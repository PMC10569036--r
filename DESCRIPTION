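Package: partprint
Title: Solvent-Water Partition Fingerprints and Substructure Prediction for Non-Targeted Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes solvent-water partition fingerprints (log K_SW / log D_SW)
    from aligned LC-MS peak-area tables, fills missing panel entries by
    randomized read-across multilinear regression against a reference
    database, standardizes fingerprints so that ionization offsets cancel,
    and converts fingerprints into predicted substructure-count vectors with
    a deep feed-forward neural network. A fully synthetic panel simulator
    (latent-descriptor fingerprint generation, ionization offsets, lognormal
    area noise, blank signal, detection dropout, and saturating detector
    response) makes every pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
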
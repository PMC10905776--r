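Package: tomospec
Title: Bi-Directional Hierarchical Latent-Structure Reconstruction of Fruit
    Tissue Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tomography-like chemometrics toolkit for Vis-NIR fruit
    spectroscopy. Tissue-level spectra (skin, pulp, seed) are decomposed into
    latent structures by principal component analysis, fused dimension-wise
    into a superset latent space, and associated with the latent space of the
    whole-fruit spectrum, so that a whole-fruit spectrum can be reconstructed
    from its tissues and, conversely, decomposed into per-tissue spectra.
    Includes logarithm multiplicative scatter correction, randomization tests
    for component selection, leave-one-out cross-validated model sizing,
    NIPALS partial least squares and principal component regression for
    quality-parameter prediction, band-ratio pigment indices for chlorophyll
    and lycopene, and a synthetic generator of paired tissue and whole-fruit
    maturation spectra.
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
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
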
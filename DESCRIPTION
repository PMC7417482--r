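Package: shotgunlipidr
Title: Quantitative Shotgun Lipidomics of Yeast with Acyl-Chain Pairing
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for species-level shotgun lipidomics of
    Saccharomyces cerevisiae: shorthand lipid nomenclature parsing,
    signal-to-noise and blank identification filters, mol% compositional
    normalization at the whole-lipidome, category, and class level,
    acyl-chain feature profiles (total length, total double bonds, chain
    usage), acyl-chain pairing matrices quantifying the selectivity with
    which saturated medium chains pair with saturated long chains
    (asymmetric lipids), stress-versus-control differential abundance with
    error propagation and unpaired t-tests, species-level principal
    component analysis, and exponential (Malthusian) growth-curve fitting
    of OD600 time courses. A synthetic-data module generates lipidome
    tables and growth curves with known ground truth so every estimator
    can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
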
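Package: selindex
Title: Multi-Trait Selection Indices for Plant and Animal Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction and evaluation of multi-trait selection indices
    for breeding programs. Estimates phenotypic (P) and genotypic (G)
    variance-covariance matrices, broad-sense heritabilities and
    genetic/phenotypic correlations from balanced randomized complete
    block (RCBD) trials via expected mean squares and mean cross-products;
    builds the Smith-Hazel optimum index (b = P^-1 G a), the Brim base
    index (b = a) and the Pesek-Baker desired-gains index (b = G^-1 d)
    under pluggable economic-weight schemes (unit weights, trait-target
    correlations, stepwise-regression standardized betas); scores and
    ranks genotypes, selects at a given intensity, and evaluates each
    index by its accuracy R_HI, aggregate gain, per-trait expected gains,
    relative efficiency against direct selection, and index coefficient
    of variation. Includes a seeded multivariate-normal RCBD trial
    simulator with known ground truth and a command-line interface over
    CSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
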
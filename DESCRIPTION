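Package: msatland
Title: Multi-Scale Landscape Genetics for Microsatellite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-scale population and landscape genetics with
    codominant microsatellite genotypes: GenAlEx-format input/output and
    filtering, per-site diversity and inbreeding statistics, exact
    Hardy-Weinberg and permutation linkage-disequilibrium tests, global and
    pairwise differentiation (Nei F_ST and Hedrick's standardized G'ST) with
    resampling significance, Bruvo's stepwise-mutation genetic distance,
    great-circle and circuit-theory (effective resistance) landscape
    distances over reclassified land-cover rasters, multiple regression on
    distance matrices (MRDM) with permutation inference for
    isolation-by-distance and isolation-by-resistance model suites, and
    fine-scale spatial autocorrelation of Loiselle kinship with jackknife
    and permutation envelopes. Includes a forward-time simulator of
    spatially structured microsatellite genotypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
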
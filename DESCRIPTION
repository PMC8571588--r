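Package: guavapop
Title: Microsatellite Population Genetics and Coalescent ABC for Island
    Invasion Routes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to trace the origin and island-to-island dispersal of an
    invasive plant from diploid SSR (microsatellite) genotypes.  Provides
    null-allele-aware diversity and distance statistics (EM estimation of
    null-allele frequencies, ENA-corrected FST, chord distances with a
    virtual null-allele class), rarefaction allelic richness, permutation
    tests with false-discovery-rate control, AMOVA, Mantel tests and
    neighbor-joining population trees with locus bootstraps, a backward-time
    coalescent simulator for unlinked SSR loci under stepwise mutation with
    colonization scenarios (splits, admixtures, founder-flush bottlenecks),
    an approximate Bayesian computation engine for scenario choice and
    parameter posteriors, a library of colonization scenario sets, and a
    synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    ape,
    vegan,
    geosphere,
    nnet,
    MASS,
    yaml,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
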
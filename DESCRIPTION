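Package: seedcapture
Title: Genetic Capture of Wild Populations in Ex Situ Seed Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how completely seed collections represent the allelic
    diversity of the wild source populations they were sampled from, using
    codominant (e.g. microsatellite) genotypes of population plants and of
    seeds collected from maternal bunches. Provides diversity indices
    (rarefied allelic richness, private alleles, multilocus genotype counts,
    Shannon/Simpson/evenness, observed and expected heterozygosity, Fis),
    incidence-based richness extrapolation (bootstrap, Chao2, first-order
    jackknife), allele accumulation curves over collection units with 70%/90%
    capture targets, distance-based AMOVA with permutation tests, Nei (1972)
    genetic distances with complete-linkage dendrograms, Mantel tests for
    isolation by distance, and a mixed-mating (selfing, outcrossing,
    apomixis) simulator of differentiated populations and seed bunches for
    method validation and sampling-strategy design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
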
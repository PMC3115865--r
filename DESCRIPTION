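Package: rangediv
Title: Range-Wide Population Genetic Diversity, Mating System and Structure Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of co-dominant microsatellite genotypes and
    mitochondrial haplotypes sampled across a species range: per-population
    expected heterozygosity and rarefied allelic/haplotype richness,
    Weir-Cockerham F_ST with Mantel tests and minimum spanning trees,
    identity-disequilibrium (g2) selfing-rate estimation, heterozygosity-excess
    bottleneck tests under a two-phase microsatellite mutation model,
    construction of biogeographic predictors (distance to range margin,
    environmental marginality, expansion classes), all-subsets linear model
    selection with AIC and Akaike weights, and permutation contrasts of
    differentiation among population classes. Includes a forward-time
    metapopulation simulator with mixed mating, founder-effect range expansion
    and distance-independent jump dispersal that provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
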
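Package: recland
Title: Fine-Scale Recombination Landscapes, Hotspots, and GC-Biased Gene
    Conversion
Version: 0.1.0
Authors@R:
    person("recland", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing fine-scale recombination landscapes in
    genomes that lack a functional PRDM9 hotspot positioner. Provides
    genetic-map input/output and hotspot calling with interval-overlap
    randomization tests; construction of composition-matched
    hotspot/coldspot control pairs; exact k-mer motif enrichment with
    Fisher tests and Bonferroni correction; outgroup-based allele
    polarization and GC-biased gene conversion (BGC) skew profiles with
    bootstrap confidence bands; feature-centred recombination-rate
    profiles and windowed composition correlations; and a synthetic
    genome/polymorphism simulator with a controllable transmission-bias
    model so every pipeline stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
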
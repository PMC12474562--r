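Package: salmonrun
Title: Run-Timing Phenology, Structure-Aware Association, and Climate
    Genomic Offset for Salmon Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-level analysis of Atlantic salmon migration
    phenology and its genomic basis. Computes run-timing descriptors (5th,
    50th and 95th percentile days of year, modality) from daily fish-count
    series, fits multi-year trends with Year-by-Site interactions, performs
    structure-aware genome-wide association by partial redundancy analysis
    and ridge latent factor mixed models, maps candidate SNPs to genes within
    a distance window, and estimates trait-specific genomic offsets under
    future climate using gradient-forest allele-frequency turnover functions.
    Includes Weir-Cockerham FST and per-population diversity metrics, and a
    synthetic-data generator that reproduces the hierarchical population
    structure, climate clines, and seasonal count curves the analysis
    assumes, so every stage can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    emmeans,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
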
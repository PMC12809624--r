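Package: planktime
Title: Assembly Processes, Seasonality and Network Dynamics in Microbial
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies the ecological processes structuring microbial
    communities sampled repeatedly at fixed observatories. Implements the
    phylogenetic and taxonomic null-model framework (beta mean nearest
    taxon distance, beta nearest taxon index, Raup-Crick on Bray-Curtis)
    that partitions community turnover into heterogeneous selection,
    homogeneous selection, historical contingency, non-selective low
    turnover and ecological drift; Lomb-Scargle detection of seasonal
    amplicon sequence variants on unevenly sampled series with
    permutation significance; indicator-species and occupancy-based ASV
    categorisation; alpha/beta diversity with distance-based PERMANOVA
    variance partitioning; and monthly temporal subnetwork topology of
    static association networks with metric-environment correlations. A
    synthetic two-observatory generator (neutral drift versus seasonal
    selection, phylogenetically conserved niches) makes every stage
    testable without sequence data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    picante,
    stats,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
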
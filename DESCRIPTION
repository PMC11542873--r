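Package: lichencensus
Title: Census of Symbionts and Bacteria in Lichen Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for censusing organismal content of lichen metagenomes from
    per-sample genome coverage and annotation tables: presence calling by
    breadth of coverage, quality filtering and ANI-based dereplication of
    metagenome-assembled genomes (MAGs), lichen fungal symbiont assignment
    and verification, frequency and prevalence tabulation across taxonomic
    ranks, multi-tier (MAG, assembly rRNA, read rRNA) detection integration,
    co-occurrence networks, a KEGG module-definition parser with block-based
    completeness evaluation, and B-vitamin prototrophy/auxotrophy
    classification with cross-feeding complementarity reports. Includes a
    seeded Lander-Waterman community simulator that emulates the statistical
    structure of lichen metagenome collections (depth-dependent MAG recovery,
    multicopy-marker detection, duplicated and misidentified samples, planted
    pathway profiles) so the whole pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
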
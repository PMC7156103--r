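Package: Dtrio
Title: Trio-Structured ABBA-BABA Tests, Admixture-Proportion Estimation,
    and Direction-of-Introgression Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies recent postspeciation introgression among
    closely related lineages using a-priori structured four-taxon ("trio")
    ABBA-BABA tests. Computes Patterson's D with block-bootstrap significance
    over tiled genomic windows, the admixture-proportion statistic Dp =
    |ABBA-BABA|/(ABBA+BABA+BBAA), and the topology-conditioned divergence
    statistic D2 for inferring the primary direction of introgression against
    a simulated null. Includes a four-taxon multispecies-coalescent simulator
    with a single introgression pulse and Jukes-Cantor sequence evolution, a
    validation grid for Dp accuracy, and a clade-wide hypothesis battery
    (sign tests on predicted D signs, regressions of Dp on genetic and
    geographic distance, and accession-disjoint trio subsets).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    vcfR,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
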
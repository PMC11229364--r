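Package: sammycomp
Title: Chromatin Compartments and Sub-Compartments from Fractionation Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs A/B chromatin compartments and an eight-level
    sub-compartment hierarchy (B.2.2 through A.1.1) from binned coverage of
    biochemically fractionated chromatin (SAMMY-seq), with a parallel Hi-C
    path (ICE balancing, observed/expected normalization, bin correlation,
    first eigenvector) for comparison. Includes concordance scoring (Jaccard
    index, eigenvector correlation, discordance classes, chromatin-state
    occupancy, per-sub-compartment mark enrichment), coverage-track plumbing
    (bedGraph/BED input, RPKM binning with read extension and blacklisting,
    rebinning, Spearman track correlation, relative enrichment, TSS effect
    sizes), and a synthetic-data generator that draws fraction tracks,
    contact matrices, genes and chromatin states from one latent openness
    field so the whole pipeline is testable end to end.
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
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
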
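Package: rerepseq
Title: Simulation and Analysis of Rerep-Seq DNA Rereplication Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for Rerep-Seq, a sequencing method that detects DNA
    rereplication by selective fragmentation of DNA carrying BrdU on both
    strands. Provides a strand-resolved generative model of BrdU labeling
    through successive cell cycles, origin firing and fork progression,
    photolysis/UDG/APE1-style nick placement with opposed-nick double-strand
    break calling and gel size selection; the normalization chain used for
    the resulting coverage tracks (reads-per-million scaling, mitochondrial
    internal-control scaling, baseline blacklist construction, fixed-width
    binning, edge-aware sliding-window smoothing, replicate averaging and
    Spearman reproducibility checks); replication-timing domain
    classification, origin-centered heatmaps, size-normalized domain
    profiles and a rank-based enrichment statistic; and the qPCR
    quantification arithmetic with the packaged primer/amplicon table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'genome.R'
    'coverage.R'
    'binning.R'
    'normalize.R'
    'simulate.R'
    'domains.R'
    'scenarios.R'
    'pipeline.R'
    'qpcr.R'
    'RcppExports.R'
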
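Package: parbseq
Title: Mapping ParB Binding Sites, Spreading and parS-Permissive Zones on
    Bacterial Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the sequencing assays used to characterise
    the ParB/parS chromosome-partitioning system of bacteria such as
    Caulobacter crescentus. Calls protein binding sites at nucleotide
    resolution from strand-specific fragment 5'-end count summits (IDAP-seq),
    builds depth-normalised ChIP-seq coverage tracks (RPBPM/RPKPM) and
    quantifies nucleation, spreading extent, peak width and asymmetry,
    estimates equilibrium dissociation constants from surface plasmon
    resonance titrations with a 1:1 binding isotherm, and maps
    parS-permissive zones from comparative Tn5 insertion libraries binned
    along the chromosome. A synthetic-data module generates toy genomes with
    planted palindromic parS sites and simulates ChIP, IDAP, transposon and
    SPR experiments with the statistical structure the analyses assume.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
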
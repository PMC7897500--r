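Package: longIS
Title: Lentiviral Integration Site Detection from Cas9-Enriched Long Reads
Version: 0.1.0
Authors@R: person("Packaging", "Team", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects lentiviral vector integration sites from amplification-free,
    Cas9-enriched Nanopore long reads. Reads that run from a provirus-internal
    guide cut site, through a vector terminus, into the host genome are
    quality- and size-filtered, triaged by a two-phase (vector-first, then
    host) alignment with repeat-aware uniqueness, and resolved into junction
    calls. Calls are clustered into unique integration sites with
    target-site-duplication estimation, annotated against a gene model
    (exon/intron/intergenic, multiple-integration genes, cross-sample gene
    overlap, chromosome-level density regression, fixed-width window binning),
    and summarised together with a fold-enrichment statistic. A self-contained
    simulator generates host genomes, planted integrations and Cas9-cut
    directional reads with ground truth, so every stage is testable without
    external data. Includes a small seed-and-chain long-read aligner so no
    external binary is required at desk scale; externally produced PAF/SAM
    alignments can be imported instead.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
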
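Package: nisinscan
Title: Genome Mining of Nisin-Like Lanthipeptide Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and characterization of nisin-like biosynthetic gene
    clusters (nBGCs) in annotated bacterial genomes. Provides a core-peptide
    sequence-pattern scanner, a position-specific log-odds profile search with
    empirical decoy calibration, gene-neighborhood extraction and machinery
    classification (LanB/LanC/LanI and companions), leader-peptide cleavage
    and core-peptide curation (deduplication, global-alignment identity
    matrices, scaffold ring/hinge mapping, dehydration mass ladders),
    composite-transposon detection and mobile-genetic-element co-localization,
    sequence-similarity networks and sharing summaries, and a seeded synthetic
    genome generator with planted ground truth for end-to-end evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'nisinscan-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'align.R'
    'seqio.R'
    'motif_scan.R'
    'corepep.R'
    'fixtures.R'
    'bgc_context.R'
    'mge.R'
    'ssn.R'
    'pipeline.R'
    'profile_model.R'
    'synthetic.R'
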
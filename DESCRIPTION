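Package: strainTrace
Title: Comparative Genomics and Ancestor Attribution for Industrial Bacterial Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of closely related bacterial
    genomes, built around the strain cohorts used in industrial amino acid
    production (Corynebacterium glutamicum and relatives). Implements
    fragment-based average nucleotide identity (ANI) with species
    demarcation, in-silico seven-locus multilocus sequence typing (MLST)
    with sequence-type assignment and allelic-profile grouping,
    pan-/core-genome rarefaction with asymptotic (Heaps-law style) curve
    fitting, whole-proteome composition-vector and core-SNP distance
    phylogenies, and ancestor-referenced variant calling with HGVS-style
    protein effect annotation. A three-step attribution pipeline (MLST
    grouping, within-group SNP phylogeny, variant annotation against the
    presumed wild-type ancestor) ties the stages together, and a seeded
    pan-genome cohort simulator provides ground-truth test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    ape,
    igraph,
    minpack.lm,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
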
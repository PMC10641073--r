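Package: broadGuide
Title: Design and Ranking of Multi-Targeting CRISPR Guide RNAs for Broad
    Genomic Regions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies single guide RNAs (gRNAs) that bind many loci
    concentrated inside large genomic windows while penalizing binding
    elsewhere. Enumerates every PAM-anchored candidate protospacer on both
    strands of a genome, finds all genomic alignments of each candidate up
    to a mismatch budget with a pigeonhole seed-and-verify mapper,
    aggregates hits into sliding windows, and ranks guides by an aggregate
    score combining on-target window scores, an off-target penalty and a
    hit-evenness term. Supports multiple target bins per guide, pooling of
    guides over shared regions, region-restricted design from BED input,
    import of external SAM alignments, and a synthetic-genome fixture
    generator with planted repeat families for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: CRISPR, SequenceMatching, Alignment, Software
RoxygenNote: 7.3.3
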
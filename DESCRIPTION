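Package: grcoverage
Title: Comparative Coverage Analysis for Germline-Restricted Sequence Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects germline-restricted (or otherwise lineage-variable)
    sequences in a genome assembly by comparing replicated germline and
    somatic DNA read coverage per contig. Each contig is treated as a single
    intronless transcript; per-sample fragment counts are converted to FPKM
    (fragments per kilobase per million mapped fragments), a germline-to-soma
    fold change and a two-group F-test with Benjamini-Hochberg FDR correction
    are computed per contig, and high-confidence germline-restricted contigs
    are called by fold-change, q-value and length thresholds. Includes
    copy-number-aware total length estimation from germline depth, a
    three-way categorisation of called sequences (high-copy, low-copy
    divergent, low-copy similar to A-chromosome paralogs), and a synthetic
    data generator with a deterministic k-mer seeded best-hit read mapper so
    the full pipeline runs without an external aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    ggplot2,
    optparse
Config/testthat/edition: 3
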
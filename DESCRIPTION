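Package: tp53junctions
Title: Exon-Exon Junction Read Analysis of TP53 Alternative Isoforms
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies TP53 alternative isoform expression from aligned
    short-read RNA-seq data using exon-exon junction reads. Classifies
    spliced alignments under a strict junction-read rule (exact breakpoint
    match, at least ten aligned nucleotides on each side of the breakpoint,
    no mismatches, at most half of the read soft-clipped), computes
    per-sample exonic fractions for the C-terminal alternative isoforms
    (p53beta family) and for the NM_001126112.2 5'UTR variant, stratifies
    samples by TP53 status (wild type, missense, truncating) from mutation
    calls, copy-number ratio and expression, and runs Bonferroni-corrected
    Welch and paired t-test comparisons between groups. Includes a full
    synthetic-data layer (toy locus, spliced-read simulator with an
    independent truth table, cohort simulator) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
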
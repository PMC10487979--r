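Package: intronarch
Title: Comparative Analysis of Exon-Intron Architecture Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of gene architecture evolution in
    ortholog families: per-gene descriptive metrics (length, GC content by
    codon position, splice-site census, intron-length distributions),
    projection of intron positions into protein-alignment coordinates and
    clustering into homologous intron sites, ancestral reconstruction of
    intron presence/absence by Dollo and constrained Fitch parsimony,
    detection of partial gene duplications by seeded local alignment of
    exons against the gene and its flanks, quantification of transposable
    element content of introns, and classification of alternative-splicing
    events among transcripts. Includes a synthetic ortholog-family
    simulator that evolves a multi-exon gene along a species tree with
    logged intron gains and losses, transposable-element insertions,
    partial duplications and isoform operations, emitting standard formats
    (FASTA, GFF3, GTF, Newick, RepeatMasker .out) plus a ground-truth log
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
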
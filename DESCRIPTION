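Package: lncscent
Title: Identification of Floral-Scent-Related Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering long non-coding RNAs
    (lncRNAs) linked to floral volatile emission in rose. Implements
    internal-standard GC-MS quantification of volatile emission rates, a
    five-filter lncRNA identification cascade (housekeeping ncRNA removal,
    exon-count filter, protein-alignment filter, length/ORF filter, and a
    protein-domain/coding-potential gate with a built-in Fickett-based
    heuristic), positional classification of lncRNAs against a coding
    annotation, cis (genomic distance) and trans (expression correlation)
    target prediction, stage-wise differential expression with core-lncRNA
    calling, and a weighted co-expression network (soft-threshold adjacency,
    topological overlap, dynamic branch cutting, module eigengenes, and
    module-trait correlation against individual scent compounds). A seeded
    synthetic-data generator emits complete fixture bundles with a
    ground-truth manifest so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
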
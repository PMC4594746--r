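Package: lncloc
Title: Identification, Classification and Expression Analysis of Long
    Noncoding RNAs from Assembled Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for discovering and characterising long noncoding
    RNAs (lncRNAs) from assembled transcript models. Filters an assembled
    GTF down to lncRNA candidates using length, exon-count and open
    reading frame rules together with externally produced coding-evidence
    lists; classifies candidates by genomic location against a
    protein-coding reference annotation using a seven-class scheme
    (intergenic, intronic sense/antisense, exonic sense/antisense, shared
    splice junction, unclassified) and names them accordingly; summarises
    structural features (exon counts, transcript/exon/intron lengths,
    alternative splicing); calls specifically and differentially
    expressed lncRNAs from FPKM matrices; and tests co-expression between
    lncRNAs and their neighbouring protein-coding genes against a
    random-pair null. A synthetic-fixture generator with planted ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
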
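Package: pancscreen
Title: Discovery and Characterization of Promoter-Associated Noncoding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Strand-aware analysis of divergent (bidirectional-promoter)
    transcription from directional RNA-seq. Quantifies antisense reads in
    promoter windows to call promoter-associated noncoding RNAs (pancRNAs),
    screens pancRNA/mRNA pairs for co-expression and coordinated regulation
    across developmental stages, profiles strand-asymmetric placement of a
    CT-rich promoter motif by position weight matrix scanning, detects CpG
    islands, and analyses bisulfite-subclone DNA methylation with exact and
    approximate Mann-Whitney U tests. Includes a deterministic synthetic-data
    generator (genome, annotation, stranded reads, planted motifs and CpG
    islands, bisulfite clones) with ground-truth tables so the full pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
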
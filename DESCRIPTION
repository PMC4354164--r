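Package: lincseek
Title: Identification and Characterization of Multi-Exon Long Intergenic
    Non-Coding RNAs from Assembled Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying long intergenic
    non-coding RNAs (lincRNAs) from assembled transcript models (GTF plus
    genome FASTA). Implements a seven-stage filter cascade (size and exon
    count, protein-coding gene overlap, coding-potential scoring from open
    reading frame features, protein-similarity and protein-domain hit
    filters, small-RNA family removal, and UTR-fragment removal), a
    protein-coding transcript classifier, structural and repeat-element
    characterization, nearest protein-coding neighbor collection,
    cross-species conservation analysis (built-in nucleotide homology
    search and chain-based liftover remapping), and quantification math
    for qPCR validation assays (2^-ddCt relative expression, RIP
    percent-input enrichment, nuclear/cytoplasmic fractionation ratios).
    A deterministic synthetic-data generator plants transcripts of known
    classes in a toy genome so that every pipeline stage is testable with
    ground truth and no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
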
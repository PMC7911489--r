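Package: trimtail
Title: Quantification of miRNA 3' Trimming and Tailing from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies 3' end modification of mature miRNAs from
    adapter-trimmed small RNA sequencing libraries. Reads are reduced to
    unique-sequence count tables, reads matching a genome in which mature
    miRNA loci have been masked are removed, and the remainder are
    classified against the mature guide and star sequences as unaltered,
    trimmed, tailed or trimmed-and-tailed by a 5'-anchored match allowing
    up to seven positions of truncation and seven of nontemplated tail.
    Per-miRNA trimming and tailing indexes (fraction of reads modified,
    each read counting once), index differences against a reference line,
    paired t-tests pairing per-miRNA mean indexes and Benjamini-Hochberg
    FDR correction grouped by modification reproduce the downstream
    statistics. A synthetic small RNA-seq generator with known truncation
    and tailing parameters supports end-to-end validation, and reporting
    helpers export index-difference boxplot data and per-locus
    reads-per-million coverage profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
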
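# Shared sequence helpers. All user-facing sequences are DNA uppercase;
# RNA input (miRBase-style) is canonicalized U->T at load time.

DNA_BASES <- c("A", "C", "G", "T")

#' Canonicalize sequences to uppercase DNA
#'
#' Uppercases and converts U to T so that miRBase-style RNA sequences and
#' FASTQ reads live in one alphabet.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector, uppercase DNA.
#' @export
#' @examples
#' canonicalize_seq("ucGAu")
canonicalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Reverse complement of DNA character vectors
#'
#' @param x Character vector of A/C/G/T(/N) sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-ACGT characters (first offender: %s)",
      what, x[which(bad)[1]]
    ))
  }
  invisible(x)
}

# Count exact occurrences of each query (forward + reverse complement) in a
# DNAStringSet genome. Ns in the subject never match (fixed = TRUE).
genome_hit_counts <- function(queries, genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  vapply(queries, function(q) {
    fwd <- sum(Biostrings::vcountPattern(q, genome, fixed = TRUE))
    rev <- sum(Biostrings::vcountPattern(revcomp(q), genome, fixed = TRUE))
    fwd + rev
  }, integer(1), USE.NAMES = FALSE)
}

# First hit of a query in the genome, searching both strands.
# Returns NULL when absent, else list(chrom, start, strand).
genome_first_hit <- function(query, genome) {
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") query else revcomp(query)
    hits <- Biostrings::vmatchPattern(pat, genome, fixed = TRUE)
    n_per_chrom <- lengths(hits)
    if (any(n_per_chrom > 0)) {
      i <- which(n_per_chrom > 0)[1]
      rng <- hits[[i]][1]
      return(list(
        chrom = names(genome)[i],
        start = IRanges::start(rng),
        strand = strand
      ))
    }
  }
  NULL
}

sig_stars <- function(q) {
  dplyr::case_when(
    is.na(q) ~ "",
    q < 0.001 ~ "***",
    q < 0.01 ~ "**",
    q < 0.05 ~ "*",
    TRUE ~ ""
  )
}
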
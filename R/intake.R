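# Read intake: collapse adapter-trimmed FASTQ to unique-sequence counts and
# remove reads that match the masked genome exactly (on either strand).

#' Collapse a FASTQ file to unique-sequence counts
#'
#' Reduces adapter-trimmed reads to a count per unique sequence, keeping
#' only reads whose length falls in `[min_len, max_len]`. Reads containing
#' N are dropped (they cannot be classified unambiguously). Quality scores
#' are never used. Gzipped input is read transparently.
#'
#' The default length gate (18-32 nt) reflects plant small-RNA libraries
#' where mature miRNAs are 20-24 nt. When trimming depths up to 7 must be
#' observable on 20-nt matures, lower `min_len` to 13.
#'
#' @param fastq Path to a FASTQ file (optionally gzipped).
#' @param min_len,max_len Length gate, inclusive.
#' @param sample_id,replicate_id Optional labels carried in the result.
#' @return A tibble with columns `sequence` and `count` (plus `sample_id` /
#'   `replicate_id` if given), one row per unique retained sequence.
#'   Attributes `n_input`, `n_length_filtered`, `n_with_n` record the intake
#'   accounting; `sum(count) + n_length_filtered + n_with_n == n_input`.
#' @export
dedupe_reads <- function(fastq, min_len = 18L, max_len = 32L,
                         sample_id = NULL, replicate_id = NULL) {
  n_lines <- length(readLines(fastq, warn = FALSE))
  if (n_lines %% 4 != 0) {
    abort(sprintf(
      "malformed FASTQ '%s': truncated record %d (%d lines, not a multiple of 4)",
      fastq, n_lines %/% 4 + 1, n_lines
    ))
  }
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq", with.qualities = FALSE),
    error = function(e) {
      abort(sprintf("malformed FASTQ '%s': %s", fastq, conditionMessage(e)))
    }
  )
  seqs <- as.character(reads)
  seq_count_table(seqs, min_len, max_len, sample_id, replicate_id)
}

# Shared by dedupe_reads and the in-memory simulation route.
seq_count_table <- function(seqs, min_len = 18L, max_len = 32L,
                            sample_id = NULL, replicate_id = NULL) {
  seqs <- canonicalize_seq(seqs)
  n_input <- length(seqs)
  has_n <- grepl("N", seqs, fixed = TRUE)
  len_ok <- nchar(seqs) >= min_len & nchar(seqs) <= max_len
  n_with_n <- sum(has_n & len_ok)
  n_len <- sum(!len_ok)
  if (n_len > 0 || n_with_n > 0) {
    inform(sprintf(
      "dedupe: %d read(s) outside [%d,%d] nt and %d N-containing read(s) dropped",
      n_len, min_len, max_len, n_with_n
    ))
  }
  keep <- seqs[len_ok & !has_n]
  tab <- if (length(keep) == 0) {
    tibble(sequence = character(), count = integer())
  } else {
    tibble(sequence = keep) %>%
      count(.data$sequence, name = "count") %>%
      arrange(dplyr::desc(.data$count), .data$sequence)
  }
  if (!is.null(replicate_id)) tab <- mutate(tab, replicate_id = replicate_id, .before = 1)
  if (!is.null(sample_id)) tab <- mutate(tab, sample_id = sample_id, .before = 1)
  attr(tab, "n_input") <- n_input
  attr(tab, "n_length_filtered") <- n_len
  attr(tab, "n_with_n") <- n_with_n
  tab
}

#' Remove sequences that match the masked genome
#'
#' Partitions a count table into sequences with no exact match in the
#' masked genome (retained: candidate unaltered/trimmed/tailed miRNAs) and
#' sequences matching it perfectly on either strand (removed: ordinary
#' genomic small RNAs). Masked (`N`) positions never match, so reads from
#' the miRNA loci themselves are retained.
#'
#' @param table Count table from [dedupe_reads()].
#' @param masked A `masked_genome` from [mask_genome()].
#' @return List with tibbles `retained` and `removed`; together they
#'   partition the input rows and conserve `sum(count)`.
#' @export
filter_genome_matching <- function(table, masked) {
  stopifnot(inherits(masked, "masked_genome"))
  if (nrow(table) == 0) {
    return(list(retained = table, removed = table))
  }
  hits <- genome_hit_counts(table$sequence, masked$seqs)
  list(
    retained = table[hits == 0, , drop = FALSE],
    removed = table[hits > 0, , drop = FALSE]
  )
}

#' Write a count table as TSV
#'
#' @param table Count table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
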
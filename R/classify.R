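# 5'-anchored classification of unique read sequences against mature
# references. A read is compatible with a reference m under (t, u) when
#   length(read) = length(m) - t + u,
#   read[1 : length(m) - t] == m[1 : length(m) - t],
# with trimming t and tail length u each bounded (default 7). The
# decomposition is canonical: t and u derive from the maximal matching
# prefix, so a tail never begins with the base that would extend the match
# and t + u is minimal for that reference. Among compatible references the
# one with minimal t + u wins; a tie between distinct references is
# "ambiguous" and excluded from index computation downstream.

#' Classify unique sequences against mature miRNA references
#'
#' Assigns each unique sequence a reference, a trim length, a tail sequence
#' and a category: `unaltered`, `trimmed`, `tailed`, `trimmed_tailed`,
#' `ambiguous` (two references tie at minimal total modification) or
#' `unclassified` (no reference compatible within the bounds). Only the 3'
#' end is modelled: the 5' end must match the reference exactly, which is
#' how 3' isomiRs are defined here.
#'
#' @param table Count table tibble with at least columns `sequence`,
#'   `count`; extra columns (sample labels) are carried through.
#' @param refs Mature reference tibble (`ref_id`, `sequence`); sequences
#'   must be distinct.
#' @param max_trim,max_tail Maximum positions of trimming / tailing
#'   considered (default 7 each, bounded independently).
#' @return The input tibble with added columns `ref_id`, `trim_len`,
#'   `tail_seq`, `category`.
#' @export
classify_table <- function(table, refs, max_trim = 7L, max_tail = 7L) {
  stopifnot(nrow(refs) > 0)
  if (anyDuplicated(refs$sequence)) {
    abort("reference sequences must be distinct (collapse identical matures first)")
  }
  assert_dna(refs$sequence, "reference")
  if (nrow(table) == 0) {
    return(mutate(table,
      ref_id = character(), trim_len = integer(),
      tail_seq = character(), category = character()
    ))
  }
  assert_dna(table$sequence, "read")

  seqs <- table$sequence
  ls <- nchar(seqs)
  n <- length(seqs)

  best_s <- rep(Inf, n)
  best_ref <- rep(NA_character_, n)
  best_t <- rep(NA_integer_, n)
  best_u <- rep(NA_integer_, n)
  tied <- rep(FALSE, n)

  for (j in seq_len(nrow(refs))) {
    m <- refs$sequence[j]
    lm <- nchar(m)
    # maximal matching prefix length k, restricted to k >= lm - max_trim;
    # prefix matching is monotone so scanning t downward keeps the largest k
    k <- rep(0L, n)
    for (t in seq(min(max_trim, lm - 1L), 0L)) {
      kk <- lm - t
      ok <- substr(seqs, 1L, kk) == substr(m, 1L, kk)
      k[ok] <- kk
    }
    t <- lm - k
    u <- ls - k
    compat <- k > 0L & t <= max_trim & u <= max_tail
    s <- t + u
    better <- compat & s < best_s
    equal <- compat & s == best_s
    tied[equal] <- TRUE
    tied[better] <- FALSE
    best_s[better] <- s[better]
    best_ref[better] <- refs$ref_id[j]
    best_t[better] <- t[better]
    best_u[better] <- u[better]
  }

  category <- case_when(
    is.infinite(best_s) ~ "unclassified",
    tied ~ "ambiguous",
    best_t == 0L & best_u == 0L ~ "unaltered",
    best_t >= 1L & best_u == 0L ~ "trimmed",
    best_t == 0L & best_u >= 1L ~ "tailed",
    TRUE ~ "trimmed_tailed"
  )
  assigned <- !category %in% c("ambiguous", "unclassified")
  out <- mutate(table,
    ref_id = ifelse(assigned, best_ref, NA_character_),
    trim_len = ifelse(assigned, best_t, NA_integer_),
    tail_seq = ifelse(assigned, substring(seqs, ls - best_u + 1L, ls), NA_character_),
    category = category
  )
  tally <- table(out$category)
  inform(paste0(
    "classify: ",
    paste(sprintf("%s=%d", names(tally), as.integer(tally)), collapse = ", ")
  ))
  out
}

#' Classify a single read sequence
#'
#' Scalar convenience wrapper around [classify_table()].
#'
#' @param seq A single DNA sequence (character).
#' @inheritParams classify_table
#' @return One-row tibble: `sequence`, `ref_id`, `trim_len`, `tail_seq`,
#'   `category`.
#' @export
classify_read <- function(seq, refs, max_trim = 7L, max_tail = 7L) {
  stopifnot(length(seq) == 1, nzchar(seq))
  withCallingHandlers(
    classify_table(tibble(sequence = seq, count = 1L), refs,
                   max_trim = max_trim, max_tail = max_tail) %>%
      select(-"count"),
    message = function(m) invokeRestart("muffleMessage")
  )
}

#' Write classified records as TSV
#'
#' @param records Output of [classify_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classified <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
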
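# Independent brute-force classifier: enumerates every (ref, t, u)
# decomposition with t <= max_trim, u <= max_tail, the length identity and
# a 5'-anchored prefix match, and keeps the minimal t + u per reference,
# then the minimum across references (ties between distinct references =
# ambiguous). Deliberately naive; kept independent of classify_table().
oracle_classify <- function(seq, refs, max_trim = 7, max_tail = 7) {
  best <- list(s = Inf, ref = NA_character_, t = NA_integer_, u = NA_integer_)
  tie <- FALSE
  ls <- nchar(seq)
  for (j in seq_len(nrow(refs))) {
    m <- refs$sequence[j]
    lm <- nchar(m)
    ref_best <- Inf
    ref_t <- NA_integer_
    for (t in 0:max_trim) {
      for (u in 0:max_tail) {
        if (ls != lm - t + u) next
        if (lm - t < 1) next
        if (substr(seq, 1, lm - t) != substr(m, 1, lm - t)) next
        if (t + u < ref_best) {
          ref_best <- t + u
          ref_t <- t
        }
      }
    }
    if (is.finite(ref_best)) {
      if (ref_best < best$s) {
        best <- list(s = ref_best, ref = refs$ref_id[j], t = ref_t,
                     u = ls - (lm - ref_t))
        tie <- FALSE
      } else if (ref_best == best$s) {
        tie <- TRUE
      }
    }
  }
  if (is.infinite(best$s)) {
    return(list(category = "unclassified", ref_id = NA_character_,
                trim_len = NA_integer_, tail_seq = NA_character_))
  }
  if (tie) {
    return(list(category = "ambiguous", ref_id = NA_character_,
                trim_len = NA_integer_, tail_seq = NA_character_))
  }
  tail_seq <- if (best$u > 0) substr(seq, ls - best$u + 1, ls) else ""
  category <- if (best$t == 0 && best$u == 0) {
    "unaltered"
  } else if (best$t >= 1 && best$u == 0) {
    "trimmed"
  } else if (best$t == 0) {
    "tailed"
  } else {
    "trimmed_tailed"
  }
  list(category = category, ref_id = best$ref, trim_len = best$t,
       tail_seq = tail_seq)
}

# Random Hamming-separated reference set (pairwise prefix distance > 2).
random_refs <- function(n_refs, len_range = c(20, 22), min_dist = 3) {
  seqs <- character(0)
  while (length(seqs) < n_refs) {
    cand <- paste(sample(c("A", "C", "G", "T"), sample(len_range[1]:len_range[2], 1),
                         replace = TRUE), collapse = "")
    L <- nchar(cand)
    ok <- all(vapply(seqs, function(s) {
      k <- min(nchar(s), L)
      sum(strsplit(substr(s, 1, k), "")[[1]] != strsplit(substr(cand, 1, k), "")[[1]]) >= min_dist
    }, logical(1)))
    if (ok) seqs <- c(seqs, cand)
  }
  tibble::tibble(ref_id = sprintf("ref%02d", seq_len(n_refs)), sequence = seqs)
}
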
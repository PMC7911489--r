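# Trimming/tailing indexes and downstream statistics. The index is the
# fraction of a miRNA's reads modified to any degree, each read counting
# once: a read trimmed by five bases weighs the same as one trimmed by one,
# and a trimmed-and-tailed read contributes to BOTH indexes. Index
# differences (IDs) subtract the reference line's per-miRNA mean index from
# the line's mean index; significance comes from a paired t-test pairing
# per-miRNA mean indexes, with BH correction pooled across all lines of a
# run within each modification.

MOD_CATEGORIES <- c("unaltered", "trimmed", "tailed", "trimmed_tailed")

#' Compute per-miRNA trimming and tailing indexes
#'
#' For each reference (within any grouping columns present, e.g.
#' `sample_id` / `line_id` / `replicate_id`), computes the total classified
#' read count and the trimming and tailing indexes. Ambiguous and
#' unclassified records are excluded from totals. A miRNA with zero
#' classified reads in a replicate has no row: 0/0 is undefined, not
#' evidence of zero modification.
#'
#' @param records Classified records from [classify_table()] (with `count`).
#' @param group_cols Character vector of grouping columns to keep, default
#'   the intersection of `c("sample_id", "line_id", "replicate_id")` with
#'   the columns present.
#' @param min_total Minimum classified read count for a row to be emitted
#'   (default 1, i.e. no threshold).
#' @return Tibble with the grouping columns plus `ref_id`, `total`,
#'   `trimming_index`, `tailing_index`.
#' @export
compute_indexes <- function(records, group_cols = NULL, min_total = 1L) {
  if (is.null(group_cols)) {
    group_cols <- intersect(c("sample_id", "line_id", "replicate_id"), names(records))
  }
  records %>%
    filter(.data$category %in% MOD_CATEGORIES) %>%
    group_by(across(all_of(c(group_cols, "ref_id")))) %>%
    summarise(
      total = sum(.data$count),
      trimming_index = sum(.data$count[.data$trim_len >= 1L]) / total,
      tailing_index = sum(.data$count[nchar(.data$tail_seq) >= 1L]) / total,
      .groups = "drop"
    ) %>%
    filter(.data$total >= min_total)
}

#' Mean indexes over replicates
#'
#' Pivots an index table to long form (modification = trimming / tailing)
#' and averages over the replicates in which the index is defined,
#' reporting how many replicates contributed (`n_used`).
#'
#' @param index_table Output of [compute_indexes()], covering the
#'   replicates of one or more lines (a `line_id` column, if present, is
#'   kept as a grouping variable).
#' @return Tibble with `line_id` (if present), `ref_id`, `modification`,
#'   `mean_index`, `n_used`.
#' @export
mean_indexes <- function(index_table) {
  group_cols <- intersect("line_id", names(index_table))
  index_table %>%
    tidyr::pivot_longer(
      c("trimming_index", "tailing_index"),
      names_to = "modification", values_to = "index"
    ) %>%
    mutate(modification = sub("_index$", "", .data$modification)) %>%
    group_by(across(all_of(c(group_cols, "ref_id", "modification")))) %>%
    summarise(
      mean_index = mean(.data$index),
      n_used = dplyr::n(),
      .groups = "drop"
    )
}

#' Index differences against a reference line
#'
#' ID = line mean index - reference line mean index, per (miRNA,
#' modification); emitted only where both lines have a defined mean.
#' Positive values mean more modification than the reference.
#'
#' @param line_means,ref_means Tibbles with `ref_id`, `modification`,
#'   `mean_index` (as from [mean_indexes()], one line each).
#' @return Tibble `ref_id`, `modification`, `line_mean`, `ref_mean`,
#'   `id_value`.
#' @export
index_differences <- function(line_means, ref_means) {
  stopifnot(nrow(line_means) > 0, nrow(ref_means) > 0)
  inner_join(
    select(line_means, "ref_id", "modification", line_mean = "mean_index"),
    select(ref_means, "ref_id", "modification", ref_mean = "mean_index"),
    by = c("ref_id", "modification")
  ) %>%
    mutate(id_value = .data$line_mean - .data$ref_mean)
}

#' Paired t-test on per-miRNA mean indexes
#'
#' Pairs the per-miRNA mean indexes of a line and its reference line for
#' one modification and tests the mean difference with a two-sided paired
#' t-test. Degenerate inputs are handled explicitly: with fewer than
#' `min_pairs` pairs, or with zero-variance differences of zero mean, no
#' p-value is reported; zero-variance differences with nonzero mean are an
#' infinitely confident shift and get the machine floor p-value, flagged.
#'
#' @inheritParams index_differences
#' @param modification `"trimming"` or `"tailing"`.
#' @param min_pairs Minimum pairs to report a p-value (default 3).
#' @param line_id,reference_line_id Labels carried into the result.
#' @return One-row tibble: `line_id`, `reference_line_id`, `modification`,
#'   `n_pairs`, `mean_id`, `t_stat`, `p_value`, `note`.
#' @export
paired_index_test <- function(line_means, ref_means, modification,
                              min_pairs = 3L,
                              line_id = "line", reference_line_id = "reference") {
  mod <- modification
  pairs <- index_differences(
    filter(line_means, .data$modification == mod),
    filter(ref_means, .data$modification == mod)
  )
  d <- pairs$id_value
  n <- length(d)
  res <- tibble(
    line_id = line_id, reference_line_id = reference_line_id,
    modification = mod, n_pairs = n,
    mean_id = if (n > 0) mean(d) else NA_real_,
    t_stat = NA_real_, p_value = NA_real_, note = ""
  )
  if (n < min_pairs) {
    warn(sprintf(
      "%s vs %s (%s): only %d pair(s), fewer than min_pairs = %d; no p-value",
      line_id, reference_line_id, mod, n, min_pairs
    ))
    res$note <- "too_few_pairs"
    return(res)
  }
  # sd on a numerically-constant vector can be ~1e-17 rather than exact 0
  if (sd(d) < 1e-9 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) < 1e-12) {
      res$note <- "degenerate_zero"
    } else {
      res$p_value <- .Machine$double.xmin
      res$t_stat <- sign(mean(d)) * Inf
      res$note <- "zero_variance_nonzero_mean"
    }
    return(res)
  }
  tt <- t.test(pairs$line_mean, pairs$ref_mean, paired = TRUE)
  res$t_stat <- unname(tt$statistic)
  res$p_value <- tt$p.value
  res
}

#' Benjamini-Hochberg correction grouped by modification
#'
#' Adds `q_value` to a table of test results, correcting trimming tests
#' together and tailing tests together across every line in the table
#' (one run = one correction per modification, irrespective of any study
#' grouping). Missing p-values stay missing and do not enter the
#' correction.
#'
#' @param results Tibble of test results with `modification` and `p_value`.
#' @return `results` with `q_value` and `stars` columns.
#' @export
fdr_correct <- function(results) {
  results %>%
    group_by(.data$modification) %>%
    mutate(q_value = {
      q <- rep(NA_real_, dplyr::n())
      ok <- !is.na(.data$p_value)
      q[ok] <- p.adjust(.data$p_value[ok], method = "BH")
      q
    }) %>%
    ungroup() %>%
    mutate(stars = sig_stars(.data$q_value))
}

#' Compare lines against their reference lines
#'
#' End-to-end statistics over an index table covering several lines:
#' per-line mean indexes, index differences against each line's reference,
#' paired t-tests per (line, modification), and one BH correction per
#' modification pooled across all lines in the call.
#'
#' @param index_table Output of [compute_indexes()] with a `line_id`
#'   column.
#' @param reference_lines Named character vector mapping each non-reference
#'   `line_id` to its reference `line_id` (different lines may use
#'   different references).
#' @param min_pairs Passed to [paired_index_test()].
#' @return An object of class `tt_comparison`: list with `ids` (per-miRNA
#'   index differences), `tests` (per line x modification, FDR-corrected),
#'   and `means`. Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
compare_lines <- function(index_table, reference_lines, min_pairs = 3L) {
  stopifnot("line_id" %in% names(index_table), length(reference_lines) > 0)
  if (is.null(names(reference_lines))) {
    abort("reference_lines must be a named vector: c(line = 'reference_line')")
  }
  missing_ref <- setdiff(unname(reference_lines), index_table$line_id)
  if (length(missing_ref) > 0) {
    abort(sprintf("reference line '%s' absent from index table", missing_ref[1]))
  }
  means <- mean_indexes(index_table)

  per_line <- purrr::imap(reference_lines, function(ref_line, line) {
    lm <- filter(means, .data$line_id == line)
    rm_ <- filter(means, .data$line_id == ref_line)
    ids <- index_differences(lm, rm_) %>%
      mutate(line_id = line, reference_line_id = ref_line, .before = 1)
    tests <- bind_rows(
      paired_index_test(lm, rm_, "trimming", min_pairs, line, ref_line),
      paired_index_test(lm, rm_, "tailing", min_pairs, line, ref_line)
    )
    list(ids = ids, tests = tests)
  })

  structure(list(
    ids = bind_rows(purrr::map(per_line, "ids")),
    tests = fdr_correct(bind_rows(purrr::map(per_line, "tests"))),
    means = means
  ), class = "tt_comparison")
}

#' @export
print.tt_comparison <- function(x, ...) {
  cat(sprintf(
    "<tt_comparison> %d line comparison(s), %d index differences\n",
    nrow(x$tests) / 2L, nrow(x$ids)
  ))
  print(x$tests)
  invisible(x)
}

#' Tidy the per-test results of a line comparison
#'
#' @param x A `tt_comparison` from [compare_lines()].
#' @param ... Unused.
#' @return Tibble of per (line, modification) tests with `q_value` and
#'   significance stars.
#' @method tidy tt_comparison
#' @export
tidy.tt_comparison <- function(x, ...) {
  x$tests
}

#' One-row summary of a line comparison
#'
#' @inheritParams tidy.tt_comparison
#' @return One-row tibble: number of lines, tests, miRNAs, and significant
#'   tests at q < 0.05.
#' @method glance tt_comparison
#' @export
glance.tt_comparison <- function(x, ...) {
  tibble(
    n_lines = length(unique(x$tests$line_id)),
    n_tests = nrow(x$tests),
    n_mirnas = length(unique(x$ids$ref_id)),
    n_sig_q05 = sum(x$tests$q_value < 0.05, na.rm = TRUE)
  )
}
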
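# Plot-ready exports: per-locus normalized small-RNA coverage and index-
# difference boxplot data with significance annotation.

#' Per-locus normalized small-RNA coverage
#'
#' Places each unique read in the window by exact match of the read (plus
#' strand) or of its reverse complement (minus strand), 5'-anchored at
#' every matching offset, and accumulates read counts into a per-position
#' depth normalized to reads per million (RPM) of the whole deduplicated
#' library. Coverage is intended to be computed from the pre-filter count
#' table so that whole-locus profiles, including the miRNA*, are visible.
#'
#' @param table Count table (before genome filtering) with `sequence`,
#'   `count`.
#' @param window One-row data frame or list with `chrom`, `start`, `end`
#'   and optionally `locus_id`; coordinates 1-based inclusive by default.
#' @param genome Genome FASTA path or `DNAStringSet` (unmasked).
#' @param coords `"gff"` (1-based inclusive, default) or `"bed"` (0-based
#'   half-open) interpretation of `window`.
#' @param library_total Library size used for RPM; defaults to
#'   `sum(table$count)` and must be >= 1.
#' @param sample_id Optional label carried into the result.
#' @return A tibble of class `tt_coverage`: `locus_id`, `chrom`, `pos`
#'   (1-based genomic), `strand` of the matched placement aggregated over
#'   both (`depth_rpm` sums the two strands; `depth_fwd_rpm` /
#'   `depth_rev_rpm` split them), plus `sample_id` if given.
#' @export
locus_coverage <- function(table, window, genome, coords = c("gff", "bed"),
                           library_total = NULL, sample_id = NULL) {
  coords <- match.arg(coords)
  genome <- read_genome(genome)
  w <- as.list(window)
  start <- as.integer(w$start)
  end <- as.integer(w$end)
  if (coords == "bed") start <- start + 1L
  stopifnot(start >= 1, end >= start, w$chrom %in% names(genome))
  if (is.null(library_total)) library_total <- sum(table$count)
  if (length(library_total) != 1 || is.na(library_total) || library_total < 1) {
    abort("library_total must be >= 1 (empty library has no RPM scale)")
  }

  win_seq <- as.character(Biostrings::subseq(genome[[w$chrom]], start, end))
  width <- end - start + 1L
  fwd <- rev_ <- numeric(width)
  for (i in seq_len(nrow(table))) {
    rd <- table$sequence[i]
    cnt <- table$count[i]
    if (nchar(rd) > width) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") rd else revcomp(rd)
      m <- Biostrings::matchPattern(pat, win_seq, fixed = TRUE)
      for (k in seq_along(m)) {
        idx <- IRanges::start(m)[k]:IRanges::end(m)[k]
        if (strand == "+") fwd[idx] <- fwd[idx] + cnt else rev_[idx] <- rev_[idx] + cnt
      }
    }
  }
  scale <- 1e6 / library_total
  out <- tibble(
    locus_id = w$locus_id %||% sprintf("%s:%d-%d", w$chrom, start, end),
    chrom = w$chrom,
    pos = seq.int(start, end),
    depth_fwd_rpm = fwd * scale,
    depth_rev_rpm = rev_ * scale,
    depth_rpm = (fwd + rev_) * scale
  )
  if (!is.null(sample_id)) out <- mutate(out, sample_id = sample_id, .before = 1)
  class(out) <- c("tt_coverage", class(out))
  out
}

#' Plot a locus coverage profile
#'
#' @param object A `tt_coverage` tibble (rows from one or more samples /
#'   loci can be bound together; facets by locus, colour by sample).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tt_coverage
#' @export
autoplot.tt_coverage <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$depth_rpm))
  if ("sample_id" %in% names(object)) {
    p <- p + ggplot2::geom_area(
      ggplot2::aes(fill = .data$sample_id),
      alpha = 0.5, position = "identity"
    )
  } else {
    p <- p + ggplot2::geom_area(alpha = 0.7)
  }
  p +
    ggplot2::facet_wrap(~locus_id, scales = "free") +
    ggplot2::labs(x = "genomic position", y = "coverage (RPM)") +
    ggplot2::theme_minimal()
}

#' Export index-difference boxplot data
#'
#' One row per (line, modification, miRNA) index difference, annotated with
#' the line-level significance stars from the FDR-corrected tests
#' (`*`, `**`, `***` at q < 0.05, 0.01, 0.001), ready for a boxplot of ID
#' distributions per line.
#'
#' @param comparison A `tt_comparison` from [compare_lines()], or a list
#'   with tibbles `ids` and `tests`.
#' @param path Optional TSV output path.
#' @return The export tibble, invisibly if `path` is given.
#' @export
export_id_boxplot_data <- function(comparison, path = NULL) {
  stopifnot(nrow(comparison$ids) > 0)
  out <- comparison$ids %>%
    left_join(
      select(comparison$tests, "line_id", "modification", "q_value", "stars"),
      by = c("line_id", "modification")
    ) %>%
    select("line_id", "reference_line_id", "modification", "ref_id",
           "id_value", "q_value", "stars")
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}

#' Boxplot of index-difference distributions per line
#'
#' @param object A `tt_comparison` from [compare_lines()].
#' @param ... Unused.
#' @return A ggplot object: one box per line, faceted by modification,
#'   significance stars above each box.
#' @method autoplot tt_comparison
#' @export
autoplot.tt_comparison <- function(object, ...) {
  dat <- export_id_boxplot_data(object)
  star_dat <- dat %>%
    group_by(.data$line_id, .data$modification) %>%
    summarise(
      y = max(.data$id_value), stars = .data$stars[1], .groups = "drop"
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$line_id, y = .data$id_value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_text(
      data = star_dat,
      ggplot2::aes(y = .data$y, label = .data$stars),
      vjust = -0.6
    ) +
    ggplot2::facet_wrap(~modification) +
    ggplot2::labs(x = NULL, y = "index difference (line - reference)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
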
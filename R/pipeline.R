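# End-to-end orchestration over a sample sheet: reference preparation,
# intake, classification, indexes, line comparisons, reporting exports,
# and a manifest with per-stage read-count conservation checks.

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `line_id`, `replicate_id`,
#'   `fastq_path`, `reference_line_id` (NA for reference lines).
#' @return Validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE)
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  sheet <- as_tibble(sheet)
  needed <- c("sample_id", "line_id", "replicate_id", "fastq_path", "reference_line_id")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols) > 0) {
    abort(sprintf("sample sheet is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  refs <- unique(sheet$reference_line_id[!is.na(sheet$reference_line_id)])
  bad <- setdiff(refs, sheet$line_id)
  if (length(bad) > 0) {
    abort(sprintf("reference_line_id '%s' never appears as a line_id", bad[1]))
  }
  missing_fq <- !file.exists(sheet$fastq_path)
  if (any(missing_fq)) {
    abort(sprintf("FASTQ not found: %s", sheet$fastq_path[which(missing_fq)[1]]))
  }
  sheet
}

#' Run the full trimming/tailing pipeline
#'
#' Executes reference preparation (mask + cross-mapping exclusion), intake
#' (dedupe + masked-genome filter), classification, per-replicate indexes,
#' and line-versus-reference statistics with one BH correction per
#' modification across all comparisons of the run. All intermediate tables
#' are written as TSV under `outdir` together with a JSON manifest holding
#' parameters and per-sample read-count conservation checks
#' (`input = length_filtered + N_filtered + genome_removed + ambiguous +
#' unclassified + classified`).
#'
#' @param sample_sheet Path to a sample-sheet TSV or a tibble (see
#'   [read_sample_sheet()]).
#' @param genome Genome FASTA path or `DNAStringSet`.
#' @param annotation GFF3 path or loci tibble.
#' @param outdir Output directory (created if needed).
#' @param mature_fasta,guide_star Passed to [load_mature_refs()].
#' @param max_trim,max_tail Classifier bounds (default 7).
#' @param min_len,max_len Read length gate for [dedupe_reads()].
#' @param min_pairs Minimum pairs for a p-value (default 3).
#' @param min_total Minimum classified reads per miRNA row (default 1).
#' @return List: `refs` (with exclusion flags), `indexes`, `comparison`
#'   (a `tt_comparison` or NULL when no line has a reference), `manifest`.
#' @export
run_pipeline <- function(sample_sheet, genome, annotation, outdir,
                         mature_fasta = NULL, guide_star = NULL,
                         max_trim = 7L, max_tail = 7L,
                         min_len = 18L, max_len = 32L,
                         min_pairs = 3L, min_total = 1L) {
  sheet <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet) else validate_sample_sheet(sample_sheet)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  genome <- read_genome(genome)
  refs_all <- load_mature_refs(genome, annotation,
                               mature_fasta = mature_fasta, guide_star = guide_star)
  all_loci <- bind_rows(refs_all$member_loci)
  masked <- mask_genome(genome, all_loci)
  refs_flagged <- find_cross_mapping(refs_all, masked)
  write_exclusion_report(refs_flagged, file.path(outdir, "excluded_mirnas.tsv"))
  refs <- filter(refs_flagged, !.data$excluded)
  if (nrow(refs) == 0) abort("every mature reference cross-maps; nothing to analyse")
  write_masked_genome(masked, file.path(outdir, "masked_genome.fa"))

  per_sample <- purrr::map(seq_len(nrow(sheet)), function(i) {
    row <- sheet[i, ]
    tab <- dedupe_reads(row$fastq_path, min_len = min_len, max_len = max_len,
                        sample_id = row$sample_id)
    split <- filter_genome_matching(tab, masked)
    classified <- classify_table(split$retained, refs,
                                 max_trim = max_trim, max_tail = max_tail) %>%
      mutate(line_id = row$line_id, replicate_id = row$replicate_id)
    write_classified(classified, file.path(outdir, paste0(row$sample_id, "_classified.tsv")))

    n_cat <- function(cats) sum(classified$count[classified$category %in% cats])
    conservation <- tibble(
      sample_id = row$sample_id,
      n_input = attr(tab, "n_input"),
      n_length_filtered = attr(tab, "n_length_filtered"),
      n_with_n = attr(tab, "n_with_n"),
      n_genome_removed = sum(split$removed$count),
      n_ambiguous = n_cat("ambiguous"),
      n_unclassified = n_cat("unclassified"),
      n_classified = n_cat(MOD_CATEGORIES)
    ) %>%
      mutate(conserved = .data$n_input ==
               .data$n_length_filtered + .data$n_with_n + .data$n_genome_removed +
               .data$n_ambiguous + .data$n_unclassified + .data$n_classified)
    list(classified = classified, conservation = conservation)
  })

  classified_all <- bind_rows(purrr::map(per_sample, "classified"))
  conservation <- bind_rows(purrr::map(per_sample, "conservation"))
  if (!all(conservation$conserved)) {
    abort(sprintf(
      "read-count conservation violated for sample '%s'",
      conservation$sample_id[!conservation$conserved][1]
    ))
  }

  idx <- compute_indexes(classified_all,
                         group_cols = c("sample_id", "line_id", "replicate_id"),
                         min_total = min_total) %>%
    left_join(select(refs, "ref_id", "kind"), by = "ref_id")
  readr::write_tsv(idx, file.path(outdir, "indexes.tsv"))

  contrasts <- sheet %>%
    filter(!is.na(.data$reference_line_id), .data$line_id != .data$reference_line_id) %>%
    distinct(.data$line_id, .data$reference_line_id)
  comparison <- NULL
  if (nrow(contrasts) > 0) {
    comparison <- compare_lines(
      idx, setNames(contrasts$reference_line_id, contrasts$line_id),
      min_pairs = min_pairs
    )
    readr::write_tsv(comparison$tests, file.path(outdir, "tests.tsv"))
    export_id_boxplot_data(comparison, file.path(outdir, "id_boxplot_data.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("trimtail")),
    parameters = list(
      max_trim = max_trim, max_tail = max_tail, min_len = min_len,
      max_len = max_len, min_pairs = min_pairs, min_total = min_total
    ),
    n_refs_total = nrow(refs_all),
    n_refs_excluded = sum(refs_flagged$excluded),
    conservation = conservation
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(refs = refs_flagged, indexes = idx, comparison = comparison, manifest = manifest)
}
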
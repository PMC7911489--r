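# Reference preparation: mature miRNA loci from a GFF3 annotation, mature
# sequence extraction and family collapsing, genome masking, and exclusion
# of miRNAs whose exact sequence also occurs outside their own (masked) loci.

#' Read mature miRNA loci from a GFF3 annotation
#'
#' Keeps records whose feature type is `"miRNA"` (the Araport11 convention
#' for mature guide and star coordinates, as opposed to the primary MIR
#' transcript); all other feature types are ignored with a message giving
#' their count.
#'
#' The guide/star label is taken, in order of precedence, from a `kind`
#' attribute in the GFF3, from `guide_star` (a two-column data frame with
#' columns `locus_id`, `kind`), or from the naming convention that ids
#' ending in `*` or `-star` are star strands.
#'
#' @param annotation Path to a GFF3 file.
#' @param guide_star Optional data frame with columns `locus_id` and `kind`
#'   (`"guide"` or `"star"`) overriding label inference.
#' @return A tibble of loci: `locus_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `kind`.
#' @export
read_mirna_loci <- function(annotation, guide_star = NULL) {
  gr <- rtracklayer::import(annotation, format = "gff3")
  types <- as.character(gr$type)
  n_other <- sum(types != "miRNA")
  if (n_other > 0) {
    inform(sprintf("read_mirna_loci: ignoring %d non-miRNA feature(s)", n_other))
  }
  gr <- gr[types == "miRNA"]
  if (length(gr) == 0) {
    abort("annotation contains no records with feature type 'miRNA'")
  }
  ids <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  if (anyNA(ids)) ids[is.na(ids)] <- as.character(gr$ID)[is.na(ids)]
  loci <- tibble(
    locus_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(!loci$strand %in% c("+", "-"))) {
    abort("miRNA records must have strand '+' or '-'")
  }
  kind_attr <- gr$kind
  if (!is.null(kind_attr)) {
    loci$kind <- as.character(kind_attr)
  } else if (!is.null(guide_star)) {
    gs <- as_tibble(guide_star)
    stopifnot(all(c("locus_id", "kind") %in% names(gs)))
    loci <- left_join(loci, gs, by = "locus_id")
    if (anyNA(loci$kind)) {
      abort(sprintf(
        "guide_star table is missing locus '%s'",
        loci$locus_id[which(is.na(loci$kind))[1]]
      ))
    }
  } else {
    loci$kind <- ifelse(grepl("(\\*|-star)$", loci$locus_id), "star", "guide")
  }
  if (any(!loci$kind %in% c("guide", "star"))) {
    abort("kind labels must be 'guide' or 'star'")
  }
  loci
}

check_loci_bounds <- function(loci, genome) {
  missing_chrom <- setdiff(loci$chrom, names(genome))
  if (length(missing_chrom) > 0) {
    abort(sprintf("chromosome '%s' not present in genome", missing_chrom[1]))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  bad <- loci$start < 1 | loci$end > lens[loci$chrom] | loci$start > loci$end
  if (any(bad)) {
    b <- loci[which(bad)[1], ]
    abort(sprintf(
      "locus '%s' (%s:%d-%d) falls outside its chromosome",
      b$locus_id, b$chrom, b$start, b$end
    ))
  }
  invisible(loci)
}

#' Load and collapse mature miRNA reference sequences
#'
#' Extracts each mature sequence strand-aware from the genome (minus-strand
#' loci are reverse-complemented) and collapses loci with byte-identical
#' mature sequences into a single reference whose id joins the member ids
#' with `/` (family members with identical matures are one unit for
#' classification). When a mature FASTA is supplied (miRBase-style, RNA
#' alphabet allowed), extracted sequences are cross-checked against it by
#' name and disagreements reported with a warning, never resolved silently.
#'
#' @param genome Path to a genome FASTA, or a `DNAStringSet`.
#' @param annotation Path to a GFF3 with `miRNA` features, or a loci tibble
#'   as returned by [read_mirna_loci()].
#' @param mature_fasta Optional path to a mature-sequence FASTA.
#' @inheritParams read_mirna_loci
#' @return A tibble with one row per distinct mature sequence: `ref_id`,
#'   `sequence`, `kind`, `n_members`, and a `member_loci` list-column of
#'   per-member locus tibbles.
#' @export
load_mature_refs <- function(genome, annotation, mature_fasta = NULL,
                             guide_star = NULL) {
  genome <- read_genome(genome)
  loci <- if (is.data.frame(annotation)) {
    as_tibble(annotation)
  } else {
    read_mirna_loci(annotation, guide_star = guide_star)
  }
  check_loci_bounds(loci, genome)

  loci$sequence <- vapply(seq_len(nrow(loci)), function(i) {
    s <- as.character(Biostrings::subseq(
      genome[[loci$chrom[i]]], loci$start[i], loci$end[i]
    ))
    if (loci$strand[i] == "-") s <- revcomp(s)
    canonicalize_seq(s)
  }, character(1))

  if (!is.null(mature_fasta)) {
    cross_check_mature(loci, mature_fasta)
  }

  refs <- loci %>%
    group_by(.data$sequence) %>%
    summarise(
      ref_id = paste(sort(unique(.data$locus_id)), collapse = "/"),
      member_loci = list(dplyr::pick(
        "locus_id", "chrom", "start", "end", "strand", "kind"
      )),
      kind_conflict = length(unique(.data$kind)) > 1,
      kind = if (length(unique(.data$kind)) == 1) .data$kind[1] else "guide",
      n_members = dplyr::n(),
      .groups = "drop"
    )
  if (any(refs$kind_conflict)) {
    warn(sprintf(
      "identical mature sequence annotated as both guide and star for: %s (labelled guide)",
      paste(refs$ref_id[refs$kind_conflict], collapse = ", ")
    ))
  }
  refs %>%
    select("ref_id", "sequence", "kind", "n_members", "member_loci") %>%
    arrange(.data$ref_id)
}

cross_check_mature <- function(loci, mature_fasta) {
  mat <- Biostrings::readBStringSet(mature_fasta)
  mat_seq <- canonicalize_seq(as.character(mat))
  nm <- sub("\\s.*$", "", names(mat))
  idx <- match(loci$locus_id, nm)
  comparable <- !is.na(idx)
  mismatch <- comparable & loci$sequence != mat_seq[idx]
  if (any(mismatch)) {
    warn(sprintf(
      "mature FASTA disagrees with genome extraction for: %s",
      paste(loci$locus_id[mismatch], collapse = ", ")
    ))
  }
  invisible(tibble(
    locus_id = loci$locus_id[mismatch],
    extracted = loci$sequence[mismatch],
    fasta = mat_seq[idx[mismatch]]
  ))
}

read_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  g <- Biostrings::readDNAStringSet(genome)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Mask miRNA loci in a genome
#'
#' Replaces every base inside the union of the locus footprints with `N`,
#' leaving all other bases unchanged. Reads derived from mature miRNAs
#' (unaltered, trimmed or tailed) then fail to match the masked genome and
#' can be isolated for modification analysis.
#'
#' @inheritParams load_mature_refs
#' @param loci Tibble of loci (`chrom`, `start`, `end` 1-based inclusive).
#' @return An object of class `masked_genome`: list with `seqs`
#'   (a `DNAStringSet`) and `intervals` (tibble of masked intervals after
#'   union, 1-based inclusive).
#' @export
mask_genome <- function(genome, loci) {
  genome <- read_genome(genome)
  loci <- as_tibble(loci)
  if (nrow(loci) > 0) check_loci_bounds(loci, genome)

  intervals <- if (nrow(loci) == 0) {
    tibble(chrom = character(), start = integer(), end = integer())
  } else {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      loci$chrom, IRanges::IRanges(loci$start, loci$end)
    ))
    tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr)
    )
  }

  seqs <- genome
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    at <- IRanges::IRanges(iv$start, iv$end)
    seqs[[ch]] <- Biostrings::replaceAt(
      seqs[[ch]], at, Biostrings::DNAStringSet(strrep("N", IRanges::width(at)))
    )
  }
  structure(list(seqs = seqs, intervals = intervals), class = "masked_genome")
}

#' @export
print.masked_genome <- function(x, ...) {
  cat(sprintf(
    "<masked_genome> %d sequence(s), %d masked interval(s), %d bp masked\n",
    length(x$seqs), nrow(x$intervals),
    sum(x$intervals$end - x$intervals$start + 1L)
  ))
  invisible(x)
}

#' Write a masked genome to FASTA
#'
#' @param masked A `masked_genome` from [mask_genome()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_masked_genome <- function(masked, path) {
  Biostrings::writeXStringSet(masked$seqs, path)
  invisible(path)
}

#' Identify cross-mapping miRNAs to exclude
#'
#' A mature reference is excluded when its exact sequence (forward or
#' reverse complement) still occurs somewhere in the masked genome: reads
#' from such miRNAs would be absorbed by the genome-matching filter, so
#' their modification indexes would be biased and they are dropped from the
#' analysis. Near-matches are not excluded; the criterion is a perfect
#' match on either strand.
#'
#' @param refs Mature reference tibble from [load_mature_refs()].
#' @param masked A `masked_genome` from [mask_genome()].
#' @return `refs` with added columns `excluded` (logical) and, for excluded
#'   rows, one match coordinate (`match_chrom`, `match_pos`, `match_strand`).
#' @export
find_cross_mapping <- function(refs, masked) {
  stopifnot(inherits(masked, "masked_genome"), nrow(refs) > 0)
  hits <- purrr::map(refs$sequence, genome_first_hit, genome = masked$seqs)
  refs %>%
    mutate(
      excluded = !purrr::map_lgl(hits, is.null),
      match_chrom = purrr::map_chr(hits, ~ .x$chrom %||% NA_character_),
      match_pos = purrr::map_int(hits, ~ .x$start %||% NA_integer_),
      match_strand = purrr::map_chr(hits, ~ .x$strand %||% NA_character_)
    )
}

#' Write the cross-mapping exclusion report
#'
#' @param refs Output of [find_cross_mapping()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(refs, path) {
  refs %>%
    filter(.data$excluded) %>%
    select("ref_id", "kind", "sequence",
           "match_chrom", "match_pos", "match_strand") %>%
    readr::write_tsv(path)
  invisible(path)
}
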
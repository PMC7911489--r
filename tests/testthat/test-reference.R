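# Reference preparation: strand-aware extraction, family collapsing,
# masking, and cross-mapping exclusion.

test_that("mature sequences are extracted strand-aware and collapsed by identity", {
  m <- "ACGTACGTACGTACGTACGTA" # 21 nt
  genome_seq <- paste0(
    strrep("T", 10), m, strrep("G", 10),
    revcomp("TTACGTAGCTGACTGATCGAT"), strrep("C", 10), m, strrep("A", 10)
  )
  g <- write_fasta(c(chr1 = genome_seq))
  loci <- tibble::tibble(
    locus_id = c("miR165a", "miR900", "miR165b"),
    chrom = "chr1",
    start = c(11, 42, 73),
    end = c(31, 62, 93),
    strand = c("+", "-", "+"),
    kind = "guide"
  )
  refs <- quiet(load_mature_refs(g, loci))

  expect_equal(nrow(refs), 2)
  # plus strand: identity extraction; identical sequences collapse
  r165 <- refs[refs$ref_id == "miR165a/miR165b", ]
  expect_equal(r165$sequence, m)
  expect_equal(r165$n_members, 2L)
  expect_equal(nrow(r165$member_loci[[1]]), 2)
  # minus strand: reverse complement of the genomic footprint
  expect_equal(refs$sequence[refs$ref_id == "miR900"], "TTACGTAGCTGACTGATCGAT")
})

test_that("GFF3 miRNA features are read and non-miRNA features ignored with a message", {
  loci <- tibble::tibble(
    locus_id = c("miR1", "miR1*"), chrom = "chr1",
    start = c(5, 40), end = c(25, 60), strand = "+", kind = c("guide", "star")
  )
  path <- write_gff3(loci)
  # append a primary-transcript record that must be ignored
  write("chr1\ttest\tgene\t1\t80\t.\t+\t.\tID=MIR1", path, append = TRUE)
  expect_message(got <- read_mirna_loci(path), "ignoring 1 non-miRNA")
  expect_equal(nrow(got), 2)
  expect_equal(got$kind, c("guide", "star")) # star from trailing-* convention
  expect_equal(got$start, c(5, 40))
})

test_that("collapsing partitions the input loci", {
  set.seed(7)
  seqs <- c(
    a = paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = ""),
    b = paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  )
  genome_seq <- paste0("TTTTT", seqs["a"], "GGGGG", seqs["b"], "AAAAA", seqs["a"], "CCCCC")
  g <- write_fasta(c(chr1 = genome_seq))
  starts <- c(6, 32, 58)
  loci <- tibble::tibble(
    locus_id = c("x", "y", "z"), chrom = "chr1",
    start = starts, end = starts + 20, strand = "+", kind = "guide"
  )
  refs <- quiet(load_mature_refs(g, loci))
  expect_equal(sum(refs$n_members), nrow(loci))
  expect_setequal(unlist(purrr::map(refs$member_loci, "locus_id")), loci$locus_id)
})

test_that("coordinates outside the chromosome are a hard error naming the locus", {
  g <- write_fasta(c(chr1 = strrep("ACGT", 20)))
  loci <- tibble::tibble(locus_id = "bad", chrom = "chr1", start = 70,
                         end = 95, strand = "+", kind = "guide")
  expect_error(load_mature_refs(g, loci), "bad")
})

test_that("mature FASTA cross-check reports disagreements and accepts RNA alphabet", {
  m <- "ACGTACGTACGTACGTACGTA"
  g <- write_fasta(c(chr1 = paste0("TTTTT", m, "GGGGG")))
  loci <- tibble::tibble(locus_id = "miR1", chrom = "chr1", start = 6,
                         end = 26, strand = "+", kind = "guide")
  # RNA version of the same sequence: no warning
  ok_fa <- tempfile(fileext = ".fa")
  writeLines(c(">miR1", chartr("T", "U", m)), ok_fa)
  expect_no_warning(quiet(load_mature_refs(g, loci, mature_fasta = ok_fa)))
  # mismatching mature: warned, not silently resolved
  bad_fa <- tempfile(fileext = ".fa")
  writeLines(c(">miR1", chartr("T", "U", paste0("G", substr(m, 2, 21)))), bad_fa)
  expect_warning(quiet(load_mature_refs(g, loci, mature_fasta = bad_fa)),
                 "disagrees.*miR1")
})

test_that("masking replaces exactly the union of locus footprints with N", {
  g <- write_fasta(c(chr1 = "AAAACCCCGGGG"))
  masked <- mask_genome(g, tibble::tibble(
    locus_id = "l1", chrom = "chr1", start = 5, end = 8, strand = "+", kind = "guide"
  ))
  expect_equal(as.character(masked$seqs[["chr1"]]), "AAAANNNNGGGG")

  # empty locus list: identity
  masked0 <- mask_genome(g, tibble::tibble(
    chrom = character(), start = integer(), end = integer()
  ))
  expect_equal(as.character(masked0$seqs[["chr1"]]), "AAAACCCCGGGG")

  # overlapping loci: union footprint
  g2 <- write_fasta(c(chr1 = "ACGTACGTACGT"))
  masked2 <- mask_genome(g2, tibble::tibble(
    chrom = "chr1", start = c(3, 5), end = c(6, 9)
  ))
  s2 <- as.character(masked2$seqs[["chr1"]])
  expect_equal(s2, "ACNNNNNNNCGT")
  expect_equal(Biostrings::countPattern("N", masked2$seqs[["chr1"]]), 7)

  # locus beyond chromosome end: hard error
  expect_error(mask_genome(g2, tibble::tibble(
    locus_id = "far", chrom = "chr1", start = 10, end = 30
  )), "far")
})

test_that("masking is idempotent", {
  g <- write_fasta(c(chr1 = strrep("ACGTGCTA", 10)))
  loci <- tibble::tibble(chrom = "chr1", start = c(9, 41), end = c(29, 61))
  once <- mask_genome(g, loci)
  twice <- mask_genome(once$seqs, loci)
  expect_equal(as.character(once$seqs), as.character(twice$seqs))
})

test_that("cross-mapping refs are excluded and clean refs retained with zero residual hits", {
  set.seed(11)
  m_clean <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  m_dup <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  # m_dup planted verbatim in an unmasked region; m_clean occurs only at its locus
  genome_seq <- paste0("TTTTT", m_clean, "GG", m_dup, "CC", m_dup, "AAAAA")
  g <- write_fasta(c(chr1 = genome_seq))
  loci <- tibble::tibble(
    locus_id = c("clean", "dup"), chrom = "chr1",
    start = c(6, 29), end = c(26, 49), strand = "+", kind = "guide"
  )
  refs <- quiet(load_mature_refs(g, loci))
  masked <- mask_genome(g, loci)
  flagged <- find_cross_mapping(refs, masked)

  expect_true(flagged$excluded[flagged$ref_id == "dup"])
  expect_false(flagged$excluded[flagged$ref_id == "clean"])
  expect_equal(flagged$match_pos[flagged$ref_id == "dup"], 52L)

  # retained refs have zero exact hits (either strand) in the masked genome
  retained <- flagged[!flagged$excluded, ]
  expect_true(all(trimtail:::genome_hit_counts(retained$sequence, masked$seqs) == 0))

  # exclusion report lists one row per excluded ref with a coordinate
  rep_path <- tempfile(fileext = ".tsv")
  write_exclusion_report(flagged, rep_path)
  rep <- readr::read_tsv(rep_path, show_col_types = FALSE)
  expect_equal(rep$ref_id, "dup")
  expect_equal(rep$match_chrom, "chr1")
})

test_that("a reverse-complement occurrence elsewhere also excludes", {
  set.seed(12)
  m <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  genome_seq <- paste0("TTTTT", m, "GG", revcomp(m), "AAAAA")
  g <- write_fasta(c(chr1 = genome_seq))
  loci <- tibble::tibble(locus_id = "m", chrom = "chr1", start = 6, end = 26,
                         strand = "+", kind = "guide")
  refs <- quiet(load_mature_refs(g, loci))
  flagged <- find_cross_mapping(refs, mask_genome(g, loci))
  expect_true(flagged$excluded)
  expect_equal(flagged$match_strand, "-")
})
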
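# Synthetic sRNA-seq with known 3'-modification parameters: a toy genome
# with non-overlapping MIR loci (guide + star per locus), replicated read
# libraries in which each miRNA read is independently truncated (prob
# pi_trim, truncated-geometric length) and/or tailed (prob pi_tail,
# truncated-geometric length, U-rich composition), plus genomic background
# reads that the masked-genome filter must remove. Ground truth is
# returned alongside every library.

#' Simulation configuration
#'
#' Defaults describe the validation conditions used throughout the
#' package: 20 miRNA loci of 20-22 nt, three replicates of ~2,000 reads
#' per miRNA, trimming probability 0.30 with truncated-geometric lengths,
#' tailing probability 0.10 with U-rich tails (P(T) = 0.8, reflecting
#' HESO1/URT1-style uridylation), and collision-free tails so that
#' classification recovers the simulated modification exactly.
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param n_mirnas Number of MIR loci (each contributes a guide and a star
#'   mature).
#' @param mirna_len_range Inclusive range of mature lengths.
#' @param genome_len Genome length in bp (must be >= `n_mirnas * 60`).
#' @param n_background_reads Exact genomic substrings (20-24 nt) per
#'   library, drawn from unmasked regions.
#' @param reads_per_mirna Expected reads per mature per replicate.
#' @param abund_meanlog,abund_sdlog Log-normal per-miRNA abundance spread;
#'   abundances are mean-normalized so expected depth stays
#'   `reads_per_mirna`. `abund_sdlog = 0` gives equal depth.
#' @param pi_trim,pi_tail Per-read probabilities of trimming / tailing.
#' @param trim_geom_p,tail_geom_p Geometric parameter of the length
#'   distributions, truncated at `max_mod`.
#' @param max_mod Maximum trim and tail length (7, matching the
#'   classifier's bounds).
#' @param tail_comp Named base probabilities for tail nucleotides
#'   (normalized internally).
#' @param collision_free When `TRUE` (default) the first tail base of a
#'   trimmed-and-tailed read is forced to differ from the reference base it
#'   replaces, so realized (trim, tail) survive classification unchanged.
#' @param n_replicates Replicates per line.
#' @param overdispersion Beta-jitter scale for per-replicate modification
#'   probabilities; 0 (default) disables it. When positive, each
#'   replicate's pi is drawn from Beta with mean pi and variance
#'   `overdispersion * pi * (1 - pi)`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mirnas = 20L,
                       mirna_len_range = c(20L, 22L),
                       genome_len = max(10000L, n_mirnas * 300L),
                       n_background_reads = 1000L,
                       reads_per_mirna = 2000,
                       abund_meanlog = 0,
                       abund_sdlog = 1,
                       pi_trim = 0.30,
                       pi_tail = 0.10,
                       trim_geom_p = 0.5,
                       tail_geom_p = 0.5,
                       max_mod = 7L,
                       tail_comp = c(A = 0.0667, C = 0.0667, G = 0.0667, T = 0.8),
                       collision_free = TRUE,
                       n_replicates = 3L,
                       overdispersion = 0) {
  stopifnot(
    genome_len >= n_mirnas * 60,
    pi_trim >= 0, pi_trim <= 1, pi_tail >= 0, pi_tail <= 1,
    max_mod <= 7L, max_mod >= 1L,
    all(tail_comp >= 0), abs(seed) < 2^31
  )
  cfg <- list(
    seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
    mirna_len_range = as.integer(mirna_len_range),
    genome_len = as.integer(genome_len),
    n_background_reads = as.integer(n_background_reads),
    reads_per_mirna = reads_per_mirna,
    abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
    pi_trim = pi_trim, pi_tail = pi_tail,
    trim_geom_p = trim_geom_p, tail_geom_p = tail_geom_p,
    max_mod = as.integer(max_mod),
    tail_comp = tail_comp / sum(tail_comp),
    collision_free = isTRUE(collision_free),
    n_replicates = as.integer(n_replicates),
    overdispersion = overdispersion
  )
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Hamming distance over the shared prefix of two sequences.
prefix_hamming <- function(a, b) {
  L <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1, L), "")[[1]] != strsplit(substr(b, 1, L), "")[[1]])
}

trunc_geom_probs <- function(p, max_len) {
  pr <- p * (1 - p)^(0:(max_len - 1))
  pr / sum(pr)
}

#' Simulate a reference: genome, annotation and mature sequences
#'
#' Builds a random genome with `n_mirnas` non-overlapping MIR loci, each
#' holding a guide and a star mature on alternating strands. Rejection
#' sampling guarantees that no mature sequence occurs anywhere else in the
#' genome (either strand) and that no two matures are within prefix
#' Hamming distance 2 of each other, so classification cannot be
#' accidentally ambiguous and [find_cross_mapping()] excludes nothing.
#' Per-miRNA abundances (log-normal, mean-normalized) are drawn here so
#' that all lines of an experiment share them.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, `genome.fa`,
#'   `annotation.gff3` and `mature.fa` (RNA alphabet, miRBase-style) are
#'   written there.
#' @return List of class `sim_reference`: `genome` (`DNAStringSet`),
#'   `loci` (tibble as [read_mirna_loci()]), `mature` (tibble `ref_id`,
#'   `sequence`, `kind`, `abundance`), and file `paths` when `dir` given.
#' @export
simulate_reference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome_chars <- sample(DNA_BASES, config$genome_len, replace = TRUE)

  n <- config$n_mirnas
  loci <- tibble(
    locus_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), kind = character()
  )
  matures <- character(0)

  if (n > 0) {
    slot <- config$genome_len %/% n
    lens <- config$mirna_len_range
    for (i in seq_len(n)) {
      strand <- if (i %% 2 == 1) "+" else "-"
      accepted <- FALSE
      for (attempt in 1:100) {
        lg <- sample(lens[1]:lens[2], 1)
        ls <- sample(lens[1]:lens[2], 1)
        guide <- rand_dna(lg)
        star <- rand_dna(ls)
        sep_ok <- all(vapply(
          matures, function(m) prefix_hamming(m, guide) > 2 && prefix_hamming(m, star) > 2,
          logical(1)
        )) && prefix_hamming(guide, star) > 2
        if (sep_ok) {
          g_start <- (i - 1L) * slot + 5L
          s_start <- g_start + lg + 15L
          genome_chars[g_start:(g_start + lg - 1L)] <-
            strsplit(if (strand == "+") guide else revcomp(guide), "")[[1]]
          genome_chars[s_start:(s_start + ls - 1L)] <-
            strsplit(if (strand == "+") star else revcomp(star), "")[[1]]
          loci <- bind_rows(loci, tibble(
            locus_id = c(sprintf("simmiR%03d", i), sprintf("simmiR%03d*", i)),
            chrom = "chr1",
            start = c(g_start, s_start),
            end = c(g_start + lg - 1L, s_start + ls - 1L),
            strand = strand,
            kind = c("guide", "star")
          ))
          matures <- c(matures, guide, star)
          accepted <- TRUE
          break
        }
      }
      if (!accepted) {
        abort("rejection sampling failed; increase genome_len or reduce n_mirnas")
      }
    }
  }

  genome <- Biostrings::DNAStringSet(setNames(paste(genome_chars, collapse = ""), "chr1"))

  # Spurious occurrences elsewhere would defeat the cross-mapping guarantee;
  # with random 20+-mers in a toy genome this is vanishingly rare, but it is
  # checked, with re-draws of the whole reference on violation.
  if (n > 0) {
    hits <- genome_hit_counts(matures, mask_genome(genome, loci)$seqs)
    if (any(hits > 0)) {
      if (config$seed > 2^30) {
        abort("simulated matures cross-map repeatedly; increase genome_len")
      }
      cfg2 <- config
      cfg2$seed <- config$seed + 1000003L
      return(simulate_reference(cfg2, dir = dir))
    }
  }

  abundance <- if (n > 0) {
    a <- rlnorm(2L * n, config$abund_meanlog, config$abund_sdlog)
    a / mean(a)
  } else {
    numeric(0)
  }
  mature <- loci %>%
    transmute(
      ref_id = .data$locus_id,
      sequence = matures,
      kind = .data$kind,
      abundance = abundance
    )

  out <- structure(
    list(genome = genome, loci = loci, mature = mature, paths = NULL),
    class = "sim_reference"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      annotation = file.path(dir, "annotation.gff3"),
      mature = file.path(dir, "mature.fa")
    )
    Biostrings::writeXStringSet(genome, paths$genome)
    write_mirna_gff3(loci, paths$annotation)
    rna <- Biostrings::BStringSet(setNames(chartr("T", "U", mature$sequence), mature$ref_id))
    Biostrings::writeXStringSet(rna, paths$mature)
    out$paths <- paths
  }
  out
}

write_mirna_gff3 <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start, loci$end), strand = loci$strand
  )
  S4Vectors::mcols(gr)$source <- "trimtail_sim"
  S4Vectors::mcols(gr)$type <- "miRNA"
  S4Vectors::mcols(gr)$ID <- loci$locus_id
  S4Vectors::mcols(gr)$Name <- loci$locus_id
  S4Vectors::mcols(gr)$kind <- loci$kind
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate the reads of one library (in memory)
#'
#' Draws per-miRNA read totals (Poisson around abundance-weighted expected
#' depth), applies independent trimming and tailing per read, and appends
#' background reads that are exact genomic substrings from unmasked
#' regions. Ground truth (source reference, realized trim and tail) is
#' attached per read.
#'
#' @param reference A `sim_reference` from [simulate_reference()].
#' @param config A [sim_config()] (per-line parameters such as `pi_trim`
#'   can be overridden via `override`).
#' @param override Named list of config fields to override for this line
#'   (e.g. `list(pi_trim = 0.45)` for a mutant).
#' @param seed Integer seed for this library.
#' @return Tibble with one row per read: `sequence`, `ref_id` (NA for
#'   background), `trim_len`, `tail_seq`.
#' @export
simulate_reads <- function(reference, config, override = list(), seed = config$seed) {
  stopifnot(inherits(reference, "sim_reference"))
  cfg <- config
  cfg[names(override)] <- override
  set.seed(as.integer(seed %% 2^31))

  mat <- reference$mature
  read_rows <- vector("list", nrow(mat) + 1L)
  trim_probs <- trunc_geom_probs(cfg$trim_geom_p, cfg$max_mod)
  tail_probs <- trunc_geom_probs(cfg$tail_geom_p, cfg$max_mod)
  comp <- cfg$tail_comp

  pi_trim <- cfg$pi_trim
  pi_tail <- cfg$pi_tail
  if (cfg$overdispersion > 0) {
    pi_trim <- rbeta_mean_var(1, pi_trim, cfg$overdispersion)
    pi_tail <- rbeta_mean_var(1, pi_tail, cfg$overdispersion)
  }

  for (i in seq_len(nrow(mat))) {
    m <- mat$sequence[i]
    lm <- nchar(m)
    n_reads <- rpois(1, cfg$reads_per_mirna * mat$abundance[i])
    if (n_reads == 0) next
    trimmed <- rbinom(n_reads, 1, pi_trim) == 1
    tailed <- rbinom(n_reads, 1, pi_tail) == 1
    t_len <- integer(n_reads)
    t_len[trimmed] <- sample.int(cfg$max_mod, sum(trimmed), replace = TRUE, prob = trim_probs)
    u_len <- integer(n_reads)
    u_len[tailed] <- sample.int(cfg$max_mod, sum(tailed), replace = TRUE, prob = tail_probs)

    tails <- character(n_reads)
    need <- which(u_len > 0)
    if (length(need) > 0) {
      all_bases <- sample(DNA_BASES, sum(u_len[need]), replace = TRUE, prob = comp)
      first_pos <- cumsum(c(1L, u_len[need][-length(need)]))
      if (cfg$collision_free) {
        # the base that would extend the 5'-anchored match back into the ref
        cont <- substring(m, lm - t_len[need] + 1L, lm - t_len[need] + 1L)
        bad <- which(t_len[need] >= 1L & all_bases[first_pos] == cont)
        while (length(bad) > 0) {
          all_bases[first_pos[bad]] <- sample(DNA_BASES, length(bad),
                                              replace = TRUE, prob = comp)
          bad <- bad[all_bases[first_pos[bad]] == cont[bad]]
        }
      }
      grp <- rep(seq_along(need), u_len[need])
      tails[need] <- vapply(split(all_bases, grp), paste, character(1), collapse = "")
    }
    read_rows[[i]] <- tibble(
      sequence = paste0(substring(m, 1L, lm - t_len), tails),
      ref_id = mat$ref_id[i],
      trim_len = t_len,
      tail_seq = tails
    )
  }

  if (cfg$n_background_reads > 0) {
    masked <- mask_genome(reference$genome, reference$loci)$seqs[["chr1"]]
    g <- as.character(masked)
    glen <- nchar(g)
    bg <- character(cfg$n_background_reads)
    filled <- 0L
    guard <- 0L
    while (filled < cfg$n_background_reads && guard < 50L * cfg$n_background_reads) {
      guard <- guard + 1L
      L <- sample(20:24, 1)
      s <- sample.int(glen - L + 1L, 1)
      sub <- substr(g, s, s + L - 1L)
      if (!grepl("N", sub, fixed = TRUE)) {
        filled <- filled + 1L
        bg[filled] <- if (runif(1) < 0.5) sub else revcomp(sub)
      }
    }
    read_rows[[nrow(mat) + 1L]] <- tibble(
      sequence = bg[seq_len(filled)],
      ref_id = NA_character_, trim_len = NA_integer_, tail_seq = NA_character_
    )
  }

  bind_rows(read_rows)
}

rbeta_mean_var <- function(n, mean, phi) {
  # Beta with given mean and variance phi * mean * (1 - mean)
  nu <- 1 / phi - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

#' Simulate one library to FASTQ with its truth table
#'
#' @inheritParams simulate_reads
#' @param line_id,replicate_id Labels for the library.
#' @param dir Output directory; writes
#'   `<line_id>_<replicate_id>.fastq.gz` and a matching `_truth.tsv`.
#' @return List: `fastq` path, `truth_tsv` path, `truth` tibble (per-read),
#'   `summary` tibble of realized per-reference modification fractions.
#' @export
simulate_library <- function(reference, config, line_id, replicate_id,
                             dir, override = list(), seed = config$seed) {
  reads <- simulate_reads(reference, config, override = override, seed = seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("%s_%s", line_id, replicate_id)
  fastq <- file.path(dir, paste0(stem, ".fastq.gz"))
  truth_tsv <- file.path(dir, paste0(stem, "_truth.tsv"))

  con <- gzfile(fastq, "wb")
  writeLines(paste0(
    "@", stem, "_", seq_len(nrow(reads)), "\n",
    reads$sequence, "\n+\n",
    strrep("I", nchar(reads$sequence))
  ), con, sep = "\n")
  close(con)

  truth <- mutate(reads, line_id = line_id, replicate_id = replicate_id, .before = 1)
  readr::write_tsv(truth, truth_tsv)

  summary <- truth %>%
    filter(!is.na(.data$ref_id)) %>%
    group_by(.data$ref_id) %>%
    summarise(
      n_reads = dplyr::n(),
      frac_trimmed = mean(.data$trim_len >= 1L),
      frac_tailed = mean(nchar(.data$tail_seq) >= 1L),
      .groups = "drop"
    )
  list(fastq = fastq, truth_tsv = truth_tsv, truth = truth, summary = summary)
}

#' Simulate a replicated multi-line experiment
#'
#' Writes the reference (genome, GFF3, mature FASTA), one FASTQ + truth
#' table per line x replicate, and a sample sheet suitable for
#' [run_pipeline()]. All lines share the reference and per-miRNA
#' abundances; per-line modification parameters come from `lines`.
#'
#' @param config A [sim_config()].
#' @param lines Tibble with `line_id` and optional `pi_trim`, `pi_tail`
#'   overrides, plus a `reference_line_id` column naming each line's
#'   comparison reference (NA for reference lines themselves).
#' @param dir Output directory.
#' @return List: `reference` (`sim_reference`), `sample_sheet` tibble
#'   (also written to `sample_sheet.tsv`), `truth` (bound per-read truth).
#' @export
simulate_experiment <- function(config, lines, dir) {
  stopifnot(inherits(config, "sim_config"), nrow(lines) >= 1)
  reference <- simulate_reference(config, dir = dir)
  sheet <- list()
  truths <- list()
  k <- 0L
  for (i in seq_len(nrow(lines))) {
    override <- as.list(lines[i, intersect(c("pi_trim", "pi_tail"), names(lines)), drop = FALSE])
    override <- override[!vapply(override, is.na, logical(1))]
    for (r in seq_len(config$n_replicates)) {
      k <- k + 1L
      lib <- simulate_library(
        reference, config,
        line_id = lines$line_id[i], replicate_id = sprintf("rep%d", r),
        dir = dir, override = override,
        seed = config$seed + 7919L * k
      )
      sheet[[k]] <- tibble(
        sample_id = sprintf("%s_rep%d", lines$line_id[i], r),
        line_id = lines$line_id[i],
        replicate_id = sprintf("rep%d", r),
        fastq_path = lib$fastq,
        reference_line_id = if ("reference_line_id" %in% names(lines)) {
          lines$reference_line_id[i]
        } else {
          NA_character_
        }
      )
      truths[[k]] <- lib$truth
    }
  }
  sample_sheet <- bind_rows(sheet)
  readr::write_tsv(sample_sheet, file.path(dir, "sample_sheet.tsv"))
  list(reference = reference, sample_sheet = sample_sheet, truth = bind_rows(truths))
}
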
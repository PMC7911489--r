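# In-code fixture builders for tiny genomes, annotations and FASTQs.

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

write_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  if (length(seqs) == 0) {
    file.create(path)
    return(path)
  }
  writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
  path
}

write_gff3 <- function(loci, path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3", sprintf(
    "%s\ttest\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
    loci$chrom, loci$start, loci$end, loci$strand, loci$locus_id, loci$locus_id
  ))
  writeLines(lines, path)
  path
}

# One 21-nt reference used across classifier examples.
M1 <- "ACGTACGTACGTACGTACGTA"
M1_REFS <- tibble::tibble(ref_id = "M1", sequence = M1)

quiet <- function(expr) {
  withCallingHandlers(expr, message = function(m) invokeRestart("muffleMessage"))
}
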
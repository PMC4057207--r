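# plain-text I/O: FASTA/FASTQ via Biostrings, annotations as BED/GFF/TSV

#' Write the toy genome as wrapped FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a genome FASTA into the package's plain-character representation
#'
#' @param path FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write simulated reads as a FASTQ pair
#'
#' @param reads A `paseq_reads` (or pooled) list with `r1`, `r2`, `qual1`,
#'   `qual2` components.
#' @param r1_path,r2_path Output FASTQ files (Phred+33).
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  w1 <- Biostrings::DNAStringSet(reads$r1)
  w2 <- Biostrings::DNAStringSet(reads$r2)
  Biostrings::writeXStringSet(w1, r1_path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual1))
  Biostrings::writeXStringSet(w2, r2_path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual2))
  invisible(c(r1_path, r2_path))
}

#' Read a FASTQ pair back into sequence vectors
#'
#' @param r1_path,r2_path FASTQ files.
#' @return List with named character vectors `r1` and `r2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  f1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  f2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  list(r1 = setNames(as.character(f1), sub("\\s.*$", "", names(f1))),
       r2 = setNames(as.character(f2), sub("\\s.*$", "", names(f2))))
}

# 1-based closed intervals -> BED 0-based half-open
bed_frame <- function(df, name, score = 0L) {
  data.frame(chrom = df$contig, chromStart = df$start - 1L,
             chromEnd = df$end, name = name, score = score,
             strand = if ("strand" %in% names(df)) df$strand else ".",
             stringsAsFactors = FALSE)
}

#' Write the annotation set and truth table to plain-text files
#'
#' Genes, repeats and snoRNAs go to BED6 (0-based half-open on disk; the
#' in-memory representation is 1-based closed), hairpins to GFF3 (1-based),
#' rRNA processing sites and the truth table to TSV.
#'
#' @param annotations,truth From [build_toy_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_annotation_set <- function(annotations, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  wbed <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE,
                                     col.names = FALSE)
  wbed(bed_frame(annotations$genes, annotations$genes$gene_id), "genes.bed")
  wbed(bed_frame(annotations$repeats, annotations$repeats$repeat_id),
       "repeats.bed")
  wbed(bed_frame(annotations$snornas,
                 paste(annotations$snornas$sno_id,
                       annotations$snornas$copy_group, sep = "|")),
       "snorna.bed")
  hp <- annotations$hairpins
  gff <- data.frame(seqid = hp$contig, source = "pasurveil",
                    type = "miRNA_primary_transcript",
                    start = hp$start, end = hp$end, score = ".",
                    strand = hp$strand, phase = ".",
                    attributes = sprintf("ID=%s;cluster=%s", hp$mirna,
                                         hp$cluster_id),
                    stringsAsFactors = FALSE)
  writeLines(c("##gff-version 3",
               apply(gff, 1, paste, collapse = "\t")),
             file.path(dir, "hairpins.gff"))
  wtsv(annotations$rrna_sites, "rrna_sites.tsv")
  wtsv(truth, "truth.tsv")
  invisible(dir)
}

#' Write a site table as TSV plus strand-split bedGraph tracks
#'
#' @param tbl Site table ([tally_hits()]); long format.
#' @param dir Output directory.
#' @param value `"raw"` or `"rpm"` track values.
#' @return `dir`, invisibly.
#' @export
write_site_tracks <- function(tbl, dir, value = c("raw", "rpm")) {
  value <- match.arg(value)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(tbl, file.path(dir, "sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  dt <- data.table::as.data.table(tbl)
  if (!value %in% names(dt)) stop_config("column '", value, "' not present")
  for (s in unique(dt$sample_id)) {
    for (st in c("+", "-")) {
      sub <- dt[sample_id == s & strand == st]
      f <- file.path(dir, sprintf("%s_%s_%s.bedGraph", s, value,
                                  if (st == "+") "plus" else "minus"))
      bg <- data.frame(sub$contig, sub$pos - 1L, sub$pos, sub[[value]])
      write.table(bg[order(bg[[1]], bg[[2]]), ], f, sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Write called peaks as a narrowPeak-style BED
#'
#' Columns: chrom, start (0-based), end, name, score (focal-sample total),
#' strand, mode (1-based), width95, narrow flag.
#'
#' @param peaks Peak table from [call_peaks()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- data.frame(peaks$contig, peaks$start - 1L, peaks$end,
                    peaks$cluster_id, peaks$total_focal, peaks$strand,
                    peaks$mode_pos, peaks$width95, as.integer(peaks$narrow))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
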
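#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (possibly gzipped).
#' @return Tibble: `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = names(x), sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::PhredQuality(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write collapsed unique reads as FASTA with count headers
#'
#' Headers follow the `seq{i}_x{count}` convention of collapsed small-RNA
#' FASTA files.
#'
#' @param collapsed Output of [collapse_unique()].
#' @param path Output path.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  ids <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)), collapsed$total)
  write_fasta(setNames(collapsed$sequence, ids), path)
}

#' Write an annotation track as BED
#'
#' @param track Tibble with `contig`, `start`, `end` and a name/class column
#'   (fourth BED column).
#' @param path Output path.
#' @param name_col Column written as the BED name field.
#' @export
write_bed <- function(track, path, name_col = "class") {
  bed <- track[, c("contig", "start", "end", name_col)]
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write planted or discovered precursors as GFF3
#'
#' Emits gene -> precursor -> mature sub-features.
#'
#' @param truth Tibble with `feature_id`, `contig`, `start`, `end`,
#'   `strand`, and precursor-relative mature spans (as in the simulation
#'   truth table).
#' @param path Output path.
#' @export
write_gff3 <- function(truth, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    P <- r$end - r$start
    g1 <- r$start + 1 # GFF is 1-based inclusive
    lines <- c(lines,
      sprintf("%s\ttormir\tgene\t%d\t%d\t.\t%s\t.\tID=gene-%s",
              r$contig, g1, r$end, r$strand, r$feature_id),
      sprintf("%s\ttormir\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene-%s",
              r$contig, g1, r$end, r$strand, r$feature_id, r$feature_id))
    for (arm in c("5p", "3p")) {
      s <- r[[paste0("mature", arm, "_start")]]
      e <- r[[paste0("mature", arm, "_end")]]
      gse <- if (r$strand == "+") c(r$start + s, r$start + e)
             else c(r$start + P - e + 1, r$start + P - s + 1)
      lines <- c(lines,
        sprintf("%s\ttormir\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s-%s;Parent=%s",
                r$contig, gse[1], gse[2], r$strand, r$feature_id, arm,
                r$feature_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a full simulation to disk
#'
#' Writes the genome FASTA, truth TSV, precursor GFF3, decoy BED tracks and
#' the known-mature FASTA.
#'
#' @param sim A `tormir_simulation`.
#' @param outdir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- c(genome = file.path(outdir, "genome.fa"),
         truth = file.path(outdir, "truth.tsv"),
         gff = file.path(outdir, "precursors.gff3"),
         ncrna = file.path(outdir, "ncrna.bed"),
         repeats = file.path(outdir, "repeats.bed"),
         known = file.path(outdir, "known_mature.fa"))
  Biostrings::writeXStringSet(sim$genome, p[["genome"]])
  readr::write_tsv(sim$truth, p[["truth"]])
  write_gff3(sim$truth, p[["gff"]])
  write_bed(rename(sim$ncrna, class = "subclass"), p[["ncrna"]])
  write_bed(sim$repeats, p[["repeats"]])
  write_fasta(setNames(sim$known_mature$sequence, sim$known_mature$mirna_id),
              p[["known"]])
  invisible(p)
}
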
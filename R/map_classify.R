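#' Build a genome index for exact read mapping
#'
#' Wraps the genome as a [Biostrings::DNAStringSet]; exact matching on both
#' strands is delegated to Biostrings' string-matching kernels.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @return An object of class `tormir_genome_index`.
#' @export
genome_index <- function(genome) {
  gs <- if (inherits(genome, "DNAStringSet")) genome
  else Biostrings::DNAStringSet(genome)
  if (is.null(names(gs))) names(gs) <- sprintf("contig%d", seq_along(gs))
  structure(list(genome = gs), class = "tormir_genome_index")
}

#' Map unique reads to the genome exactly, on both strands
#'
#' Every exact occurrence is reported; a minus-strand hit means the reverse
#' complement of the read matches the forward genome at that interval.
#' Coordinates are 0-based half-open.
#'
#' @param reads Tibble with a `sequence` column (unique reads), or a
#'   character vector of sequences.
#' @param index A [genome_index()].
#' @return Tibble of hits: `sequence`, `contig`, `start`, `end`, `strand`.
#' @export
map_reads <- function(reads, index) {
  seqs <- if (is.character(reads)) unique(reads) else unique(reads$sequence)
  empty <- tibble(sequence = character(0), contig = character(0),
                  start = integer(0), end = integer(0), strand = character(0))
  if (!length(seqs)) return(empty)
  out <- list()
  # constant-width pattern dictionaries per read length for fast multi-
  # pattern matching; the minus strand searches the reverse complements
  by_width <- split(seqs, nchar(seqs))
  for (grp in by_width) {
    for (strand in c("+", "-")) {
      pats <- if (strand == "+") grp else revcomp(grp)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
      for (ci in seq_along(index$genome)) {
        m <- Biostrings::matchPDict(pd, index$genome[[ci]])
        n_hit <- lengths(m)
        if (!sum(n_hit)) next
        ir <- unlist(m)
        out[[length(out) + 1]] <- tibble(
          sequence = rep(grp, n_hit),
          contig = names(index$genome)[ci],
          start = IRanges::start(ir) - 1L,
          end = IRanges::end(ir), strand = strand)
      }
    }
  }
  if (!length(out)) return(empty)
  arrange(bind_rows(out), .data$sequence, .data$contig, .data$start,
          .data$strand)
}

#' Apply the multi-locus and singleton filters
#'
#' Reads hitting the genome at more than `max_loci` positions are removed
#' (likely repeat-derived multi-mappers), as are reads whose summed count
#' across libraries is below `min_count` (sequencing noise).
#'
#' @param collapsed Tibble of unique reads with a `total` count column.
#' @param hits Tibble of genome hits from [map_reads()].
#' @param max_loci Maximum tolerated number of genomic loci (inclusive).
#' @param min_count Minimum total count (inclusive).
#' @return The retained unique reads with an `n_loci` column;
#'   `attr(, "removed")` records removals by reason.
#' @export
filter_hits <- function(collapsed, hits, max_loci = 20, min_count = 2) {
  nl <- count(hits, .data$sequence, name = "n_loci")
  x <- inner_join(collapsed, nl, by = "sequence")
  too_many <- x$n_loci > max_loci
  too_few <- x$total < min_count
  removed <- bind_rows(
    mutate(x[too_many, c("sequence", "total", "n_loci")], reason = "multi_locus"),
    mutate(x[!too_many & too_few, c("sequence", "total", "n_loci")],
           reason = "singleton")
  )
  out <- x[!too_many & !too_few, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Match reads against a known mature miRNA set
#'
#' A read matches a known mature when, at some end offset of at most
#' `end_slack` nt on each side (the read may be a sub- or super-string of
#' the mature), the Hamming distance over the overlapping bases is at most
#' `max_mismatch`. The best match minimises distance; ties go to the
#' lexicographically smallest identifier.
#'
#' @param sequences Character vector of read sequences (or tibble with a
#'   `sequence` column).
#' @param known Tibble with `mirna_id` and `sequence`.
#' @param max_mismatch Maximum Hamming distance over the overlap.
#' @param end_slack Maximum end-offset (nt) on each side.
#' @return Tibble: `sequence`, `mirna_id` (NA when unmatched), `mismatches`.
#' @export
match_known_mirna <- function(sequences, known, max_mismatch = 2,
                              end_slack = 2) {
  if (!is.character(sequences)) sequences <- sequences$sequence
  if (nrow(known) == 0) {
    return(tibble(sequence = sequences, mirna_id = NA_character_,
                  mismatches = NA_integer_))
  }
  known <- arrange(known, .data$mirna_id)
  best_id <- rep(NA_character_, length(sequences))
  best_d <- rep(NA_integer_, length(sequences))
  for (i in seq_along(sequences)) {
    r <- sequences[i]
    nr <- nchar(r)
    for (j in seq_len(nrow(known))) {
      m <- known$sequence[j]
      nm <- nchar(m)
      if (abs(nr - nm) > 2 * end_slack) next
      for (off in -end_slack:end_slack) {
        # align read position 1 to mature position 1 + off
        r_end_off <- (off + nr) - nm # read end relative to mature end
        if (abs(off) > end_slack || abs(r_end_off) > end_slack) next
        lo <- max(1, 1 + off); hi <- min(nm, nr + off)
        if (hi - lo + 1 < nm - 2 * end_slack) next
        d <- hamming(substr(r, lo - off, hi - off), substr(m, lo, hi))
        if (d <= max_mismatch && (is.na(best_d[i]) || d < best_d[i])) {
          best_d[i] <- d
          best_id[i] <- known$mirna_id[j]
        }
      }
    }
  }
  tibble(sequence = sequences, mirna_id = best_id, mismatches = best_d)
}

CLASS_LEVELS <- c("known_miRNA", "rRNA", "tRNA", "snoRNA", "snRNA",
                  "other_ncRNA", "transcript", "LINE", "SINE", "LTR", "DNA",
                  "SSR", "Low", "unknown_repeat", "unknown")

# is any read hit interval fully inside an annotation interval of the track?
interval_class <- function(hits_per_seq, track) {
  function(s) {
    h <- hits_per_seq[[s]]
    if (is.null(h) || nrow(track) == 0) return(NA_character_)
    for (i in seq_len(nrow(h))) {
      inside <- track$contig == h$contig[i] & track$start <= h$start[i] &
        h$end[i] <= track$end
      if (any(inside)) return(track$class[which(inside)[1]])
    }
    NA_character_
  }
}

# exact containment of the read (either strand) in a set of reference seqs
containment_class <- function(refs, classes) {
  function(s) {
    rc <- revcomp(s)
    hit <- vapply(refs, function(ref) grepl(s, ref, fixed = TRUE) ||
                    grepl(rc, ref, fixed = TRUE), logical(1))
    if (any(hit)) classes[which(hit)[1]] else NA_character_
  }
}

#' Classify retained reads into annotation classes
#'
#' Assigns exactly one class per read by sequential precedence: known miRNA
#' (<= 2 mismatches against the known mature set), then ncRNA subclass
#' (exact containment in an ncRNA reference sequence, either strand), then
#' transcript (same rule), then repeat class (the read's genomic interval
#' entirely within a repeat interval), else `"unknown"`.
#'
#' @param retained Tibble of retained unique reads (`sequence` plus count
#'   columns from [collapse_unique()]).
#' @param hits Genome hits for those reads.
#' @param known_mature Tibble (`mirna_id`, `sequence`) or NULL.
#' @param ncrna Tibble (`sequence`, `subclass`) of ncRNA references or NULL;
#'   subclasses must be rRNA/tRNA/snoRNA/snRNA/other_ncRNA.
#' @param transcripts Character vector of transcript sequences or NULL.
#' @param repeats Tibble (`contig`, `start`, `end`, `class`) or NULL; classes
#'   must be LINE/SINE/LTR/DNA/SSR/Low/Unknown.
#' @return The input tibble with a `class` column.
#' @export
classify_reads <- function(retained, hits, known_mature = NULL, ncrna = NULL,
                           transcripts = NULL, repeats = NULL) {
  if (!is.null(ncrna) && nrow(ncrna) > 0) {
    bad <- setdiff(unique(ncrna$subclass),
                   c("rRNA", "tRNA", "snoRNA", "snRNA", "other_ncRNA"))
    if (length(bad)) abort(paste("unknown ncRNA subclass:", paste(bad, collapse = ", ")))
  }
  if (!is.null(repeats) && nrow(repeats) > 0) {
    bad <- setdiff(unique(repeats$class),
                   c("LINE", "SINE", "LTR", "DNA", "SSR", "Low", "Unknown"))
    if (length(bad)) abort(paste("unknown repeat class:", paste(bad, collapse = ", ")))
    repeats <- mutate(repeats,
                      class = if_else(.data$class == "Unknown",
                                      "unknown_repeat", .data$class))
  }
  seqs <- retained$sequence
  cls <- rep(NA_character_, length(seqs))

  if (!is.null(known_mature) && nrow(known_mature) > 0) {
    km <- match_known_mirna(seqs, known_mature)
    cls[!is.na(km$mirna_id)] <- "known_miRNA"
  }
  if (!is.null(ncrna) && nrow(ncrna) > 0) {
    f <- containment_class(ncrna$sequence, ncrna$subclass)
    todo <- which(is.na(cls))
    cls[todo] <- vapply(seqs[todo], f, character(1))
  }
  if (!is.null(transcripts) && length(transcripts) > 0) {
    f <- containment_class(transcripts, rep("transcript", length(transcripts)))
    todo <- which(is.na(cls))
    cls[todo] <- vapply(seqs[todo], f, character(1))
  }
  if (!is.null(repeats) && nrow(repeats) > 0) {
    hs <- split(hits[, c("contig", "start", "end")], hits$sequence)
    f <- interval_class(hs, repeats)
    todo <- which(is.na(cls))
    cls[todo] <- vapply(seqs[todo], f, character(1))
  }
  cls[is.na(cls)] <- "unknown"
  mutate(retained, class = cls)
}

#' Tabulate classified reads per class and library
#'
#' @param classified Output of [classify_reads()] with per-library count
#'   columns.
#' @param libraries Library column names; defaults to all count columns.
#' @return Tibble: `class`, `library`, `unique_reads`, `total_reads`, plus an
#'   `"overall"` library aggregating all.
#' @export
classification_table <- function(classified, libraries = NULL) {
  libraries <- libraries %||%
    setdiff(names(classified), c("sequence", "class", "total", "n_loci"))
  long <- classified |>
    pivot_longer(all_of(libraries), names_to = "library", values_to = "n") |>
    group_by(.data$class, .data$library) |>
    summarise(unique_reads = sum(.data$n > 0), total_reads = sum(.data$n),
              .groups = "drop")
  overall <- classified |>
    group_by(.data$class) |>
    summarise(unique_reads = n(),
              total_reads = sum(rowSums(dplyr::pick(all_of(libraries)))),
              .groups = "drop") |>
    mutate(library = "overall")
  bind_rows(long, overall[, names(long)])
}

#' Percentage summary of a classification table
#'
#' Computes each class's share of a denominator count, rounded to one
#' decimal, as percentages are reported in library summaries (class reads as
#' a share of perfectly matched reads; perfectly matched reads as a share of
#' clean reads).
#'
#' @param count Numerator count(s).
#' @param denominator Denominator count.
#' @param digits Rounding digits.
#' @return Percentage(s); `NA` when the denominator is zero.
#' @export
#' @examples
#' class_percentage(15068478, 31590053) # 47.7
class_percentage <- function(count, denominator, digits = 1) {
  ifelse(denominator == 0, NA_real_, round(100 * count / denominator, digits))
}

#' @rdname class_percentage
#' @param table Output of [classification_table()].
#' @param matched_totals Named vector of perfectly-matched totals per library
#'   used as denominators.
#' @export
classification_summary <- function(table, matched_totals) {
  mutate(table,
         pct_unique = class_percentage(.data$unique_reads,
                                       matched_totals[.data$library]),
         pct_total = class_percentage(.data$total_reads,
                                      matched_totals[.data$library]))
}
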
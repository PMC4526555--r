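#' Trim the 3' adapter from raw reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, provided the overlap is at least `min_overlap` nt; reads without
#' such an overlap are returned unchanged. Matching is exact — tolerance is
#' deliberately not applied so trimming is bit-stable.
#'
#' @param reads Tibble with a `sequence` column (and optionally `quality`,
#'   trimmed alongside).
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum suffix/prefix overlap (nt).
#' @return The tibble with trimmed `sequence` (and `quality`).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6) {
  if (!nzchar(adapter)) abort("adapter must be non-empty")
  adapter <- toupper(adapter)
  seqs <- toupper(reads$sequence)
  nlen <- nchar(seqs)
  kmax <- min(max(nlen), nchar(adapter))
  trim_at <- rep(0L, length(seqs)) # suffix length to remove
  if (kmax >= min_overlap) {
    for (k in seq(min_overlap, kmax)) {
      pref <- substr(adapter, 1, k)
      hit <- nlen >= k & substr(seqs, nlen - k + 1, nlen) == pref
      trim_at[hit] <- k
    }
  }
  reads$sequence <- substr(seqs, 1, nlen - trim_at)
  if ("quality" %in% names(reads)) {
    reads$quality <- substr(reads$quality, 1, nlen - trim_at)
  }
  reads
}

#' Remove short, long and ambiguous reads
#'
#' Drops reads containing N and reads outside the retained length range
#' (bounds inclusive), mirroring the 18-33 nt gel-purified insert range.
#' Removal counts per reason are attached as the `"removals"` attribute.
#'
#' @param reads Tibble with a `sequence` column (adapter-trimmed).
#' @param min_len,max_len Inclusive length bounds (nt).
#' @return The filtered tibble; `attr(, "removals")` tabulates drops.
#' @export
clean_reads <- function(reads, min_len = 18, max_len = 33) {
  n <- nchar(reads$sequence)
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  keep <- !has_n & n >= min_len & n <= max_len
  out <- reads[keep, , drop = FALSE]
  attr(out, "removals") <- tibble(
    reason = c("contains_N", "too_short", "too_long"),
    n = c(sum(has_n), sum(!has_n & n < min_len), sum(!has_n & n > max_len))
  )
  out
}

#' Collapse cleaned reads to unique sequences with per-library counts
#'
#' @param reads Tibble with `sequence` and `library` columns, one row per
#'   read.
#' @return A tibble with one row per distinct sequence, one count column per
#'   library, and a `total` column; sorted by decreasing total.
#' @export
collapse_unique <- function(reads) {
  libs <- sort(unique(reads$library))
  out <- reads |>
    count(.data$sequence, .data$library) |>
    pivot_wider(names_from = "library", values_from = "n", values_fill = 0L)
  out$total <- rowSums(out[, libs, drop = FALSE])
  arrange(out, desc(.data$total), .data$sequence)
}

#' Library redundancy
#'
#' The fraction of reads that are duplicates of an already-seen sequence:
#' `100 * (1 - unique / total)`, in percent.
#'
#' @param n_unique Number of distinct sequences.
#' @param n_total Number of (clean) reads.
#' @return Redundancy percentage (vectorised).
#' @export
#' @examples
#' redundancy(629751, 12160105) # 94.82
redundancy <- function(n_unique, n_total) {
  if (any(n_total <= 0)) abort("total read count must be positive")
  if (any(n_unique > n_total) || any(n_unique <= 0)) {
    abort("need 0 < unique <= total")
  }
  100 * (1 - n_unique / n_total)
}

#' Per-library summary statistics
#'
#' @param clean Tibble of cleaned reads (`sequence`, `library`).
#' @return Tibble per library: `clean_reads`, `unique_reads`, `redundancy`
#'   (percent).
#' @export
library_stats <- function(clean) {
  clean |>
    group_by(.data$library) |>
    summarise(clean_reads = n(),
              unique_reads = dplyr::n_distinct(.data$sequence),
              .groups = "drop") |>
    mutate(redundancy = redundancy(.data$unique_reads, .data$clean_reads))
}

#' Read-length histogram
#'
#' @param clean Tibble of cleaned reads (`sequence`, `library`).
#' @return Tibble of counts per `library` and `length`.
#' @export
length_histogram <- function(clean) {
  clean |>
    mutate(length = nchar(.data$sequence)) |>
    count(.data$library, .data$length, name = "n")
}
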
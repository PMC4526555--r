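## Internal sequence helpers. Bases are handled as upper-case DNA (T, not U)
## everywhere internally; folding routines map T -> U on entry.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGGA"))
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# encode A=0, C=1, G=2, T/U=3 for the compiled kernels
encode_seq <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  v <- utf8ToInt(s)
  codes <- vapply(c("A", "C", "G", "T"), utf8ToInt, integer(1))
  code <- integer(length(v))
  code[v == codes[["A"]]] <- 0L
  code[v == codes[["C"]]] <- 1L
  code[v == codes[["G"]]] <- 2L
  code[v == codes[["T"]]] <- 3L
  bad <- !(v %in% codes)
  if (any(bad)) {
    abort(paste0("sequence contains non-ACGU symbols: ",
                 paste(unique(strsplit(s, "")[[1]][bad]), collapse = ", ")))
  }
  code
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# hamming distance between equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

`%||%` <- rlang::`%||%`
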
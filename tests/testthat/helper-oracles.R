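# Independent reference implementations used to validate the package's
# dynamic programming kernels and tests' fixtures. Written in plain R,
# separately from the implementations they check.

# maximum weighted nested-pairing score by memoised interval recursion
oracle_fold_score <- function(seq, weights = c(gc = 3, au = 2, gu = 1),
                              min_loop = 3) {
  b <- strsplit(chartr("TU", "UU", toupper(seq)), "")[[1]]
  n <- length(b)
  w <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% c("GC", "CG")) return(weights[["gc"]])
    if (p %in% c("AU", "UA")) return(weights[["au"]])
    if (p %in% c("GU", "UG")) return(weights[["gu"]])
    -Inf
  }
  memo <- new.env()
  rec <- function(i, j) {
    if (i >= j || j - i <= min_loop) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      wk <- w(b[i], b[k])
      if (is.finite(wk)) {
        best <- max(best, wk + rec(i + 1, k - 1) + rec(k + 1, j))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1, n)
}

# exhaustive enumeration of every nested structure (small n only); used to
# validate that the memoised recursion itself is a faithful oracle
oracle_fold_enumerate <- function(seq, weights = c(gc = 3, au = 2, gu = 1),
                                  min_loop = 3) {
  b <- strsplit(chartr("TU", "UU", toupper(seq)), "")[[1]]
  n <- length(b)
  w <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% c("GC", "CG")) return(weights[["gc"]])
    if (p %in% c("AU", "UA")) return(weights[["au"]])
    if (p %in% c("GU", "UG")) return(weights[["gu"]])
    -Inf
  }
  best <- 0
  recurse <- function(avail, score) {
    if (score > best) best <<- score
    if (!length(avail)) return()
    i <- avail[1]
    recurse(avail[-1], score) # i unpaired
    for (k in avail[-1]) {
      if (k - i <= min_loop) next
      wk <- w(b[i], b[k])
      if (!is.finite(wk)) next
      inner <- avail[avail > i & avail < k]
      outer <- avail[avail > k]
      # nested: remaining positions split into inside and outside of (i,k)
      recurse_two(inner, outer, score + wk)
    }
  }
  recurse_two <- function(inner, outer, score) {
    # solve the two independent sub-problems sequentially
    best_inner <- 0
    save <- best
    best <<- 0
    recurse(inner, 0)
    best_inner <- best
    best <<- save
    recurse(outer, score + best_inner)
  }
  recurse(seq_len(n), 0)
  best
}

# plain-R local alignment of a sequence against its reverse complement with
# linear gaps (same geometry as the inverted-repeat kernel), score only
oracle_ir_score <- function(seq, match = 3, mismatch = -3, gap = 6) {
  b <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(b)
  H <- matrix(0, n + 1, n + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      g <- n - j + 1
      if (i >= g) next
      sub <- if (b[i] == comp[[b[g]]]) match else mismatch
      h <- max(0, H[i, j] + sub, H[i, j + 1] - gap, H[i + 1, j] - gap)
      H[i + 1, j + 1] <- h
      best <- max(best, h)
    }
  }
  best
}

# naive full-scan exact mapping on both strands (0-based half-open)
oracle_map <- function(read, genome_seqs) {
  rc_read <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read)))
  out <- list()
  for (ctg in names(genome_seqs)) {
    g <- genome_seqs[[ctg]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else rc_read
      hits <- gregexpr(pat, g, fixed = TRUE)[[1]]
      # gregexpr misses overlapping occurrences; rescan from each hit + 1
      starts <- integer(0)
      from <- 1
      repeat {
        rel <- regexpr(pat, substr(g, from, nchar(g)), fixed = TRUE)
        if (rel == -1) break
        starts <- c(starts, from + rel - 1)
        from <- from + rel
      }
      for (s in starts) {
        out[[length(out) + 1]] <- data.frame(
          sequence = read, contig = ctg, start = s - 1L,
          end = s - 1L + nchar(read), strand = strand)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  do.call(rbind, out)
}

# conditional NB exact test by direct enumeration with dnbinom products
oracle_exact_nb <- function(yh, ya, phi, mu = 10) {
  s <- yh + ya
  if (s == 0) return(1)
  k <- 0:s
  w <- if (phi <= 0) {
    stats::dpois(k, mu) * stats::dpois(s - k, mu)
  } else {
    stats::dnbinom(k, size = 1 / phi, mu = mu) *
      stats::dnbinom(s - k, size = 1 / phi, mu = mu)
  }
  w <- w / sum(w)
  sum(w[w <= w[yh + 1] * (1 + 1e-10)])
}

# random DNA for fixtures
rand_dna <- function(n, gc = 0.5, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
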
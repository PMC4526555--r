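#' Inverted-repeat search parameters
#'
#' Scoring follows the classic EMBOSS einverted defaults used for miRNA
#' precursor screening: match +3, mismatch -3, gap -6 (linear), report
#' threshold 30, maximum repeat extent 240 nt. The printed magnitudes for
#' mismatch and gap are penalties.
#'
#' @param match,mismatch,gap_penalty Alignment scores (penalties positive).
#' @param threshold Minimum reported alignment score.
#' @param max_repeat_length Maximum total extent (nt) of a reported repeat.
#' @return A list of class `tormir_ir_params`.
#' @export
ir_params <- function(match = 3, mismatch = 3, gap_penalty = 6,
                      threshold = 30, max_repeat_length = 240) {
  stopifnot(threshold > 0, max_repeat_length > 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_penalty = gap_penalty, threshold = threshold,
                 max_repeat_length = max_repeat_length),
            class = "tormir_ir_params")
}

#' Find inverted repeats by local self-alignment
#'
#' Locally aligns the sequence against its own reverse complement with a
#' linear gap penalty; each alignment corresponds to the two arms of a
#' stem-loop. Non-overlapping repeats are reported best-first: after each
#' reported repeat its genomic extent is masked and the search repeats until
#' no alignment reaches the threshold. Repeats spanning more than
#' `max_repeat_length` are discarded.
#'
#' @param seq A DNA sequence (character scalar).
#' @param params An [ir_params()].
#' @return A tibble with one row per inverted repeat: 1-based inclusive
#'   `left_start`, `left_end`, `right_start`, `right_end`, `score`,
#'   `n_pairs`, and a `pairs` list-column of matched position pairs.
#' @export
find_inverted_repeats <- function(seq, params = ir_params()) {
  code <- encode_seq(seq)
  n <- length(code)
  mask <- rep(FALSE, n)
  out <- list()
  repeat {
    hit <- cpp_ir_best(code, params$match, -params$mismatch,
                       params$gap_penalty, mask)
    if (hit$score < params$threshold || length(hit$left_pos) == 0) break
    ls <- min(hit$left_pos); le <- max(hit$left_pos)
    rs <- min(hit$right_pos); re <- max(hit$right_pos)
    mask[ls:re] <- TRUE
    if (re - ls + 1 > params$max_repeat_length) next
    out[[length(out) + 1]] <- tibble(
      left_start = ls, left_end = le, right_start = rs, right_end = re,
      score = hit$score, n_pairs = length(hit$left_pos),
      pairs = list(cbind(left = hit$left_pos, right = hit$right_pos))
    )
  }
  if (!length(out)) {
    return(tibble(left_start = integer(0), left_end = integer(0),
                  right_start = integer(0), right_end = integer(0),
                  score = numeric(0), n_pairs = integer(0), pairs = list()))
  }
  bind_rows(out)
}

#' Fold an RNA sequence by weighted base-pair maximisation
#'
#' Finds the nested secondary structure maximising the weighted number of
#' base pairs (G:C = 3, A:U = 2, G:U = 1) subject to a minimum hairpin loop
#' of 3 nt, with a deterministic traceback. This topology-level model stands
#' in for full thermodynamic folding: the downstream hairpin decision depends
#' on stem/loop topology, not precise free energies.
#'
#' @param seq DNA/RNA sequence (T and U both accepted).
#' @param weights Pair weights `c(gc, au, gu)`.
#' @param min_loop Minimum unpaired hairpin-loop length (nt).
#' @param blocked Optional integer vector of 1-based positions forbidden to
#'   pair (used for accessibility calculations).
#' @return An object of class `tormir_fold`: list with `sequence`, `pairing`
#'   (0 = unpaired, else 1-based partner), `dotbracket`, `score`, `n_pairs`.
#' @export
fold_rna <- function(seq, weights = c(gc = 3, au = 2, gu = 1), min_loop = 3,
                     blocked = NULL) {
  code <- encode_seq(seq)
  blk <- rep(FALSE, length(code))
  if (!is.null(blocked)) blk[blocked] <- TRUE
  res <- cpp_fold(code, as.numeric(weights), as.integer(min_loop), blk)
  pairing <- res$pairing
  db <- rep(".", length(code))
  db[pairing > seq_along(pairing)] <- "("
  db[pairing != 0 & pairing < seq_along(pairing)] <- ")"
  structure(list(sequence = toupper(chartr("T", "U", seq)), pairing = pairing,
                 dotbracket = paste(db, collapse = ""), score = res$score,
                 n_pairs = sum(pairing > 0) / 2, weights = weights,
                 min_loop = min_loop),
            class = "tormir_fold")
}

#' @export
print.tormir_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "\n",
      sprintf("score %.1f, %d pairs\n", x$score, as.integer(x$n_pairs)), sep = "")
  invisible(x)
}

# outermost pair enclosing a terminal loop such that the enclosed interval
# still contains exactly one terminal loop (the stem, including internal
# loops and bulges, but stopping before any multiloop)
enclosing_stem <- function(pairing, loop_start, loop_end) {
  i <- loop_start - 1L
  j <- loop_end + 1L
  if (i < 1 || pairing[i] != j) return(c(i, j)) # defensive; loop is closed
  single_loop <- function(a, b) {
    sub <- pairing[a:b]
    sub <- ifelse(sub == 0, 0L, sub - a + 1L) # rebase partners to the slice
    nrow(terminal_loops(sub)) == 1
  }
  repeat {
    p <- i - 1L
    while (p >= 1 && pairing[p] == 0) p <- p - 1L
    if (p < 1 || pairing[p] <= j) break
    q <- pairing[p]
    if (!single_loop(p, q)) break
    i <- p
    j <- q
  }
  c(i, j)
}

# hairpin (terminal) loops of a pairing: closing pair (i,j) with no paired
# position strictly inside; returns a tibble of loop intervals (i+1 .. j-1)
terminal_loops <- function(pairing) {
  n <- length(pairing)
  loops <- list()
  for (i in seq_len(n)) {
    j <- pairing[i]
    if (j > i) {
      inside <- if (j - i > 1) pairing[(i + 1):(j - 1)] else integer(0)
      if (all(inside == 0)) {
        loops[[length(loops) + 1]] <- c(start = i + 1L, end = j - 1L)
      }
    }
  }
  if (!length(loops)) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  as_tibble(do.call(rbind, loops))
}

#' Check a folded precursor against canonical hairpin criteria
#'
#' A candidate passes when the structure has a single terminal loop, the
#' precursor does not exceed the maximum repeat length, the mature span lies
#' entirely within one stem arm without touching the terminal loop, at most
#' `max_unpaired_mature` mature bases are unpaired, and no asymmetric bulge
#' within the mature pairing region exceeds `max_bulge` nt. These thresholds
#' follow the published MirCheck defaults.
#'
#' @param fold A `tormir_fold` of the candidate precursor.
#' @param mature_span Integer `c(start, end)`, 1-based inclusive, within the
#'   folded sequence.
#' @param precursor_span Optional `c(start, end)` restricting the criteria to
#'   the precursor proper when the fold covers extra flanking bases (the
#'   10-nt fold extensions); defaults to the whole folded sequence.
#' @param max_precursor Maximum precursor length (nt).
#' @param max_unpaired_mature Maximum unpaired mature bases.
#' @param max_bulge Maximum asymmetric bulge (nt) within the mature region.
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   every failed criterion; empty when passing).
#' @export
check_hairpin <- function(fold, mature_span, precursor_span = NULL,
                          max_precursor = 240, max_unpaired_mature = 4,
                          max_bulge = 2) {
  n <- nchar(fold$sequence)
  precursor_span <- precursor_span %||% c(1L, n)
  if (mature_span[1] < 1 || mature_span[2] > n || mature_span[1] > mature_span[2]) {
    abort("mature span lies outside the folded structure")
  }
  reasons <- character(0)
  if (precursor_span[2] - precursor_span[1] + 1 > max_precursor) {
    reasons <- c(reasons, "exceeds maximum length")
  }
  loops <- terminal_loops(fold$pairing)
  loops <- loops[loops$start >= precursor_span[1] &
                   loops$end <= precursor_span[2], , drop = FALSE]
  if (nrow(loops) != 1) {
    reasons <- c(reasons, sprintf("%d terminal loops in the precursor span (need exactly 1)",
                                  nrow(loops)))
  }
  m <- mature_span[1]:mature_span[2]
  if (nrow(loops) >= 1) {
    lp <- loops[1, ]
    if (any(m >= lp$start & m <= lp$end)) {
      reasons <- c(reasons, "mature overlaps loop")
    } else if (!(mature_span[2] < lp$start || mature_span[1] > lp$end)) {
      reasons <- c(reasons, "mature spans the loop")
    }
  }
  unpaired <- sum(fold$pairing[m] == 0)
  if (unpaired > max_unpaired_mature) {
    reasons <- c(reasons, sprintf("%d unpaired mature bases (max %d)",
                                  unpaired, max_unpaired_mature))
  }
  paired_m <- m[fold$pairing[m] != 0]
  if (length(paired_m) >= 2) {
    for (t in seq_len(length(paired_m) - 1)) {
      p <- paired_m[t]; q <- paired_m[t + 1]
      pp <- fold$pairing[p]; qq <- fold$pairing[q]
      asym <- abs((q - p - 1) - (pp - qq - 1))
      if (asym > max_bulge) {
        reasons <- c(reasons, sprintf("asymmetric bulge of %d nt in mature region (max %d)",
                                      asym, max_bulge))
        break
      }
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Merge read loci into genomic blocks
#'
#' Read loci closer than `gap_limit` (end of the previous locus to the start
#' of the next, strictly) are chained into one maximal block, strand-agnostic,
#' so that both arms of a precursor are examined together.
#'
#' @param loci Tibble with `contig`, `start`, `end` (0-based half-open); any
#'   further columns (e.g. `sequence`) are carried through.
#' @param gap_limit Maximum inter-locus distance (nt), exclusive.
#' @return The input tibble, sorted, with a `block_id` column.
#' @export
merge_blocks <- function(loci, gap_limit = 200) {
  if (nrow(loci) == 0) return(mutate(loci, block_id = character(0)))
  loci <- arrange(loci, .data$contig, .data$start, .data$end)
  block <- integer(nrow(loci))
  cur <- 1L
  cur_end <- loci$end[1]
  cur_contig <- loci$contig[1]
  block[1] <- cur
  for (i in seq_len(nrow(loci))[-1]) {
    gap <- loci$start[i] - cur_end
    if (loci$contig[i] != cur_contig || max(gap, 0) >= gap_limit) {
      cur <- cur + 1L
      cur_end <- loci$end[i]
      cur_contig <- loci$contig[i]
    } else {
      cur_end <- max(cur_end, loci$end[i])
    }
    block[i] <- cur
  }
  mutate(loci, block_id = sprintf("%s:block%04d", .data$contig, block))
}

#' Extract genomic context around blocks
#'
#' @param blocks Tibble with `contig`, `start`, `end` per block (0-based
#'   half-open; typically `merge_blocks()` output summarised per block).
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param flank Flank size (nt) added on each side, clipped at contig bounds.
#' @return The tibble with `window_start`, `window_end`, `clipped`, `window_seq`.
#' @export
extract_context <- function(blocks, genome, flank = 150) {
  seqs <- if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else genome
  ws <- pmax(0L, blocks$start - as.integer(flank))
  clen <- nchar(seqs[blocks$contig])
  we <- pmin(as.integer(clen), blocks$end + as.integer(flank))
  mutate(blocks,
         window_start = ws, window_end = we,
         clipped = ws != .data$start - flank | we != .data$end + flank,
         window_seq = unname(substr(seqs[.data$contig], ws + 1, we)))
}

# pick the representative variant of a read stack: max total count,
# ties broken by longer sequence, then lexicographic order
representative_variant <- function(reads) {
  o <- order(-reads$total, -nchar(reads$sequence), reads$sequence)
  reads[o[1], ]
}

#' Call mature miRNAs from the read stack on a folded precursor
#'
#' Requires read support on both stem arms: each arm must carry at least one
#' unique read whose 5' start lies within +/-2 nt of the arm's (count-
#' weighted) modal start. Confidence is `"high"` when an arm carries two or
#' more unique reads inside that window, reflecting the +/-2 nt cleavage
#' bias; otherwise `"candidate"`. The representative mature per arm is the
#' variant with the highest total count (ties: longer, then lexicographic).
#'
#' @param reads Tibble of precursor-relative member reads: `sequence`,
#'   `start`, `end` (1-based inclusive within the precursor), `total` count.
#' @param fold The precursor `tormir_fold`.
#' @param loop Optional `c(start, end)` of the terminal loop anchoring the
#'   arms; by default the fold's single terminal loop (rejected when the
#'   fold has several).
#' @param offset_window Half-width of the mature-position window (nt).
#' @return `NULL` when rejected, else a list with per-arm mature calls and a
#'   confidence level.
#' @export
call_mature <- function(reads, fold, loop = NULL, offset_window = 2) {
  if (is.null(loop)) {
    loops <- terminal_loops(fold$pairing)
    if (nrow(loops) != 1) return(NULL)
    lp <- loops[1, ]
  } else {
    lp <- tibble(start = loop[1], end = loop[2])
  }
  arm_of <- function(s, e) {
    if (e < lp$start) "5p" else if (s > lp$end) "3p" else NA_character_
  }
  reads$arm <- map_chr(seq_len(nrow(reads)),
                       function(i) arm_of(reads$start[i], reads$end[i]))
  reads <- reads[!is.na(reads$arm), , drop = FALSE]
  arms <- list()
  for (a in c("5p", "3p")) {
    ar <- reads[reads$arm == a, , drop = FALSE]
    if (nrow(ar) == 0) return(NULL) # both arms required
    starts <- rep(ar$start, ar$total)
    modal <- as.integer(names(sort(table(starts), decreasing = TRUE))[1])
    in_window <- ar[abs(ar$start - modal) <= offset_window, , drop = FALSE]
    if (nrow(in_window) == 0) return(NULL)
    rep_v <- representative_variant(in_window)
    arms[[a]] <- list(mature = rep_v$sequence,
                      span = c(rep_v$start, rep_v$end),
                      n_unique = nrow(in_window),
                      n_total = sum(in_window$total),
                      modal_start = modal)
  }
  confidence <- if (arms$`5p`$n_unique >= 2 || arms$`3p`$n_unique >= 2) {
    "high"
  } else "candidate"
  list(mature5p = arms$`5p`, mature3p = arms$`3p`, confidence = confidence)
}

empty_candidates <- function() {
  tibble(candidate_id = character(0), contig = character(0),
         precursor_start = integer(0), precursor_end = integer(0),
         orientation = character(0), precursor_seq = character(0),
         structure = character(0), ir_score = numeric(0),
         mature5p_seq = character(0), mature3p_seq = character(0),
         mature5p_start = integer(0), mature5p_end = integer(0),
         mature3p_start = integer(0), mature3p_end = integer(0),
         support_unique = integer(0), support_total = numeric(0),
         confidence = character(0), novelty = character(0))
}

#' Discover miRNA hairpin precursors from candidate reads
#'
#' Runs the discovery chain: merge candidate read loci into genomic blocks,
#' extract flanking context, find inverted repeats, fold each repeat with a
#' 10-nt extension, apply the hairpin criteria, and call matures from the
#' read stack on both arms. Both orientations of each window are examined;
#' the orientation carrying the majority of read support is used for mature
#' calling. Candidates are deduplicated by genomic overlap (best-supported
#' kept) and labelled `"conserved"` when a representative mature matches the
#' known set within 2 mismatches, else `"novel"`.
#'
#' @param candidate_hits Tibble of candidate read loci: `sequence`, `contig`,
#'   `start`, `end`, `strand` (0-based half-open) — typically the unknown-
#'   class retained reads from [classify_reads()] joined to their hits.
#' @param counts Tibble with `sequence` and `total` count per unique read.
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param known_mature Tibble (`mirna_id`, `sequence`) of known matures, or
#'   `NULL`.
#' @param params An [ir_params()].
#' @param gap_limit,flank,fold_extension Pipeline geometry (nt).
#' @return A tibble of hairpin candidates (one row each) with precursor
#'   locus, structure, mature calls, support, confidence and novelty.
#' @export
discover_mirna <- function(candidate_hits, counts, genome,
                           known_mature = NULL, params = ir_params(),
                           gap_limit = 200, flank = 150, fold_extension = 10) {
  if (nrow(candidate_hits) == 0) return(empty_candidates())
  seqs <- if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else genome
  hits <- left_join(candidate_hits, counts[, c("sequence", "total")],
                    by = "sequence")
  hits$total[is.na(hits$total)] <- 1
  blocked <- merge_blocks(hits, gap_limit = gap_limit)
  blocks <- blocked |>
    group_by(.data$block_id, .data$contig) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  blocks <- extract_context(blocks, seqs, flank = flank)

  out <- list()
  for (b in seq_len(nrow(blocks))) {
    blk <- blocks[b, ]
    members <- blocked[blocked$block_id == blk$block_id, , drop = FALSE]
    irs <- find_inverted_repeats(blk$window_seq, params)
    if (nrow(irs) == 0) next
    wlen <- nchar(blk$window_seq)
    for (r in seq_len(nrow(irs))) {
      ir <- irs[r, ]
      ps <- max(1L, ir$left_start - fold_extension)
      pe <- min(wlen, ir$right_end + fold_extension)
      prec_fwd <- substr(blk$window_seq, ps, pe)
      g_start <- blk$window_start + ps - 1L   # 0-based genomic start
      g_end <- blk$window_start + pe          # half-open end
      P <- pe - ps + 1L

      # member reads inside the folded region; orientation by weighted
      # majority strand, then only strand-consistent hits are stacked
      # (a perfect stem also produces mirror-locus hits on the other strand)
      mem <- members[members$start >= g_start & members$end <= g_end, , drop = FALSE]
      if (nrow(mem) == 0) next
      minus_wt <- sum(mem$total[mem$strand == "-"])
      use_rev <- minus_wt > 0.5 * sum(mem$total)
      mem <- mem[mem$strand == (if (use_rev) "-" else "+"), , drop = FALSE]
      if (nrow(mem) == 0) next
      prec_seq <- if (use_rev) revcomp(prec_fwd) else prec_fwd
      fd <- fold_rna(prec_seq)
      # the precursor proper is the inverted repeat; the 10-nt extensions
      # only give the fold context
      span_fwd <- c(ir$left_start - ps + 1L, ir$right_end - ps + 1L)
      ir_span <- if (use_rev) c(P + 1L - span_fwd[2], P + 1L - span_fwd[1])
                 else span_fwd
      loops <- terminal_loops(fd$pairing)
      loops <- loops[loops$start >= ir_span[1] & loops$end <= ir_span[2], ,
                     drop = FALSE]
      if (nrow(loops) == 0) next
      rel <- if (!use_rev) {
        tibble(sequence = mem$sequence,
               start = mem$start - g_start + 1L, end = mem$end - g_start,
               total = mem$total)
      } else {
        tibble(sequence = mem$sequence,
               start = g_end - mem$end + 1L, end = g_end - mem$start,
               total = mem$total)
      }
      # anchor on each candidate terminal loop; the precursor span is the
      # loop's enclosing stem (exactly one terminal loop by construction)
      try_fold <- function(fd, rel, lo, hi) {
        lps <- terminal_loops(fd$pairing)
        lps <- lps[lps$start >= lo & lps$end <= hi, , drop = FALSE]
        for (li in seq_len(nrow(lps))) {
          stem <- enclosing_stem(fd$pairing, lps$start[li], lps$end[li])
          span <- c(max(1L, stem[1]), min(nchar(fd$sequence), stem[2]))
          this <- call_mature(rel, fd, loop = c(lps$start[li], lps$end[li]))
          if (is.null(this)) next
          chk5 <- check_hairpin(fd, this$mature5p$span, precursor_span = span,
                                max_precursor = params$max_repeat_length)
          chk3 <- check_hairpin(fd, this$mature3p$span, precursor_span = span,
                                max_precursor = params$max_repeat_length)
          if (chk5$pass && chk3$pass) return(this)
        }
        NULL
      }
      call <- try_fold(fd, rel, ir_span[1], ir_span[2])
      if (is.null(call)) {
        # flanking context can reorganise the optimum; refold the repeat alone
        sub_seq <- substr(prec_seq, ir_span[1], ir_span[2])
        fd_sub <- fold_rna(sub_seq)
        rel_sub <- mutate(rel, start = .data$start - ir_span[1] + 1L,
                          end = .data$end - ir_span[1] + 1L)
        rel_sub <- rel_sub[rel_sub$start >= 1 &
                             rel_sub$end <= nchar(sub_seq), , drop = FALSE]
        call <- try_fold(fd_sub, rel_sub, 1L, nchar(sub_seq))
        if (!is.null(call)) {
          # lift mature spans back to extended-fold coordinates
          for (a in c("mature5p", "mature3p")) {
            call[[a]]$span <- call[[a]]$span + ir_span[1] - 1L
          }
        }
      }
      if (is.null(call)) next
      novelty <- "novel"
      if (!is.null(known_mature) && nrow(known_mature) > 0) {
        km <- match_known_mirna(c(call$mature5p$mature, call$mature3p$mature),
                                known_mature)
        if (any(!is.na(km$mirna_id))) novelty <- "conserved"
      }
      out[[length(out) + 1]] <- tibble(
        candidate_id = NA_character_, contig = blk$contig,
        precursor_start = g_start, precursor_end = g_end,
        orientation = if (use_rev) "-" else "+",
        precursor_seq = prec_seq, structure = fd$dotbracket,
        ir_score = ir$score,
        mature5p_seq = call$mature5p$mature,
        mature3p_seq = call$mature3p$mature,
        mature5p_start = call$mature5p$span[1],
        mature5p_end = call$mature5p$span[2],
        mature3p_start = call$mature3p$span[1],
        mature3p_end = call$mature3p$span[2],
        support_unique = call$mature5p$n_unique + call$mature3p$n_unique,
        support_total = call$mature5p$n_total + call$mature3p$n_total,
        confidence = call$confidence, novelty = novelty)
    }
  }
  if (!length(out)) return(empty_candidates())
  cand <- bind_rows(out)
  # deduplicate by genomic overlap, keeping the best-supported candidate
  ord <- order(cand$contig, -cand$support_total, cand$precursor_start)
  taken <- cand[0, ]
  for (i in ord) {
    row <- cand[i, ]
    overlaps <- any(taken$contig == row$contig &
                      taken$precursor_start < row$precursor_end &
                      row$precursor_start < taken$precursor_end)
    if (!overlaps) taken <- bind_rows(taken, row)
  }
  taken <- arrange(taken, .data$contig, .data$precursor_start)
  taken$candidate_id <- sprintf("cand-%03d", seq_len(nrow(taken)))
  taken
}
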
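## Nearest-neighbour RNA stack free energies (kcal/mol at 37 C).
## Watson-Crick values follow the published Turner/Xia parameter set; stacks
## containing G:U pairs use a simplified, documented set (exact parity with
## any thermodynamic package is a non-goal; the table is swappable).
pair_codes <- c("AU", "UA", "CG", "GC", "GU", "UG")

build_stack_table <- function() {
  E <- matrix(NA_real_, 6, 6, dimnames = list(pair_codes, pair_codes))
  set <- function(p1, p2, v) {
    E[p1, p2] <<- v
    # strand-exchange symmetry: 5'p1 p2 3' == 5' flip(p2) flip(p1) 3'
    flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
    E[flip(p2), flip(p1)] <<- v
  }
  set("AU", "AU", -0.93); set("AU", "UA", -1.10); set("UA", "AU", -1.33)
  set("CG", "UA", -2.08); set("CG", "AU", -2.11); set("GC", "UA", -2.24)
  set("GC", "AU", -2.35); set("CG", "GC", -2.36); set("GC", "GC", -3.26)
  set("GC", "CG", -3.42)
  # G:U-containing stacks (simplified): weakly stabilising next to A:U,
  # moderately next to G:C, marginal for tandem G:U
  for (wc in c("AU", "UA")) {
    for (gu in c("GU", "UG")) { set(wc, gu, -0.5); set(gu, wc, -0.5) }
  }
  for (wc in c("CG", "GC")) {
    for (gu in c("GU", "UG")) { set(wc, gu, -1.5); set(gu, wc, -1.5) }
  }
  for (g1 in c("GU", "UG")) for (g2 in c("GU", "UG")) set(g1, g2, -0.4)
  E
}

#' Nearest-neighbour duplex energy model
#'
#' @param initiation Duplex initiation penalty (kcal/mol).
#' @param bulge_open,bulge_per_nt Penalty for opening a bulge/internal loop
#'   and per unpaired nt inside it (kcal/mol).
#' @param stacks Optional replacement 6x6 stack table (rows/columns AU, UA,
#'   CG, GC, GU, UG).
#' @return A list of class `tormir_energy_model`.
#' @export
energy_model <- function(initiation = 0, bulge_open = 3.0,
                         bulge_per_nt = 0.5, stacks = NULL) {
  E <- stacks %||% build_stack_table()
  wc <- c("AU", "UA", "CG", "GC")
  stopifnot(all(E[wc, wc] <= 0))
  structure(list(initiation = initiation, bulge_open = bulge_open,
                 bulge_per_nt = bulge_per_nt, stacks = E),
            class = "tormir_energy_model")
}

base_pair_code <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% pair_codes) p else NA_character_
}

#' Hybridisation free energy of a miRNA:site duplex
#'
#' Minimum free energy over antiparallel pairings of the miRNA against the
#' site context by nearest-neighbour dynamic programming: stacked pairs add
#' stack energies, bulges and internal loops pay an opening plus per-nt
#' penalty, plus the model's initiation term. The empty pairing scores 0, so
#' the result is never positive.
#'
#' @param mirna miRNA sequence, 5'->3' (DNA or RNA alphabet).
#' @param site Site context on the mRNA, 5'->3'.
#' @param model An [energy_model()].
#' @return Duplex free energy `dG_duplex` in kcal/mol (<= 0).
#' @export
duplex_energy <- function(mirna, site, model = energy_model()) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  s <- rev(strsplit(chartr("T", "U", toupper(site)), "")[[1]]) # antiparallel
  nm <- length(m)
  ns <- length(s)
  pairable <- matrix(NA_character_, nm, ns)
  for (i in seq_len(nm)) for (j in seq_len(ns)) {
    pairable[i, j] <- base_pair_code(m[i], s[j])
  }
  # D[i, j]: best energy of a pairing ending with pair (i, j)
  D <- matrix(Inf, nm, ns)
  best <- 0
  for (i in seq_len(nm)) {
    for (j in seq_len(ns)) {
      p <- pairable[i, j]
      if (is.na(p)) next
      e <- model$initiation # start a duplex at (i, j)
      if (i > 1 && j > 1) {
        for (pi in seq_len(i - 1)) {
          for (pj in seq_len(j - 1)) {
            if (!is.finite(D[pi, pj])) next
            gap_m <- i - pi - 1
            gap_s <- j - pj - 1
            loop <- if (gap_m + gap_s == 0) {
              model$stacks[pairable[pi, pj], p]
            } else {
              model$bulge_open + model$bulge_per_nt * (gap_m + gap_s)
            }
            e <- min(e, D[pi, pj] + loop)
          }
        }
      }
      D[i, j] <- e
      best <- min(best, e)
    }
  }
  best
}

#' Energetic cost of making a site accessible
#'
#' Folds a window around the site with the weighted base-pair-maximisation
#' model once unconstrained and once with the site bases forbidden to pair;
#' the difference in (weighted) structure stability, scaled to kcal/mol, is
#' the opening cost `dG_open >= 0`.
#'
#' @param utr UTR sequence.
#' @param site_start,site_end Site interval, 1-based inclusive.
#' @param window Window width (nt) centred on the site.
#' @param energy_per_weight kcal/mol per folding weight unit.
#' @return `dG_open` in kcal/mol.
#' @export
open_energy <- function(utr, site_start, site_end, window = 70,
                        energy_per_weight = 1) {
  len <- site_end - site_start + 1
  if (window < len) abort("window smaller than the site")
  n <- nchar(utr)
  half <- (window - len) %/% 2
  ws <- max(1, site_start - half)
  we <- min(n, site_end + half)
  sub <- substr(utr, ws, we)
  rel <- (site_start - ws + 1):(site_end - ws + 1)
  free <- fold_rna(sub)
  constrained <- fold_rna(sub, blocked = rel)
  max(0, (free$score - constrained$score) * energy_per_weight)
}

#' Find seed-complementary candidate sites in a UTR
#'
#' The default site is an exact Watson-Crick match of miRNA positions 2-8
#' (7mer). A site is upgraded to 8mer when the UTR base facing miRNA
#' position 1 also pairs, or is an A. 6mer sites (positions 2-7) are only
#' reported when enabled.
#'
#' @param mirna miRNA sequence, 5'->3' (>= 8 nt).
#' @param utr UTR sequence (a character scalar).
#' @param allow_6mer Also report 6mer sites.
#' @return Tibble: `site_start`, `site_end` (1-based inclusive interval of
#'   the seed-paired region plus the position-1 partner), `seed_class`.
#' @export
find_seed_sites <- function(mirna, utr, allow_6mer = FALSE) {
  mirna <- chartr("U", "T", toupper(mirna))
  utr <- chartr("U", "T", toupper(utr))
  if (nchar(mirna) < 8) abort("miRNA must be at least 8 nt")
  seed7 <- revcomp(substr(mirna, 2, 8))
  hit_starts <- function(pat) {
    g <- gregexpr(pat, utr, fixed = TRUE)[[1]]
    if (g[1] == -1) integer(0) else as.integer(g)
  }
  out <- list()
  for (p in hit_starts(seed7)) {
    facing <- substr(utr, p + 7, p + 7) # base opposite miRNA position 1
    class8 <- nzchar(facing) &&
      (facing == revcomp(substr(mirna, 1, 1)) || facing == "A")
    out[[length(out) + 1]] <- tibble(
      site_start = p, site_end = min(nchar(utr), p + 7),
      seed_class = if (class8) "8mer" else "7mer")
  }
  if (allow_6mer) {
    seed6 <- revcomp(substr(mirna, 2, 7))
    sevens <- vapply(out, function(x) x$site_start, integer(1))
    for (p in hit_starts(seed6)) {
      if ((p - 1) %in% sevens || p %in% sevens) next # subsumed by a 7mer
      out[[length(out) + 1]] <- tibble(site_start = p, site_end = p + 5,
                                       seed_class = "6mer")
    }
  }
  if (!length(out)) {
    return(tibble(site_start = integer(0), site_end = integer(0),
                  seed_class = character(0)))
  }
  arrange(bind_rows(out), .data$site_start)
}

#' Infer a 3'UTR record
#'
#' Without an ortholog UTR, the (up to) 3-kb window downstream of the coding
#' stop is the UTR. With one, the window is globally aligned to the ortholog
#' (match +1, mismatch -1, gap -2 linear) and truncated at the last window
#' position aligned to an ortholog base; the trimmed record keeps the
#' original genomic bases.
#'
#' @param downstream_seq Sequence downstream of the coding stop (may be
#'   shorter than `utr_max` near contig ends).
#' @param ortholog_utr Optional ortholog 3'UTR sequence.
#' @param utr_max Maximum UTR length (nt).
#' @return Tibble row: `sequence`, `length`, `provenance`.
#' @export
infer_utr <- function(downstream_seq, ortholog_utr = NULL, utr_max = 3000) {
  if (is.null(downstream_seq) || !nzchar(downstream_seq)) {
    abort("empty downstream sequence")
  }
  window <- substr(downstream_seq, 1, utr_max)
  if (is.null(ortholog_utr)) {
    return(tibble(sequence = window, length = nchar(window),
                  provenance = "fallback_3kb"))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(window), Biostrings::DNAString(toupper(ortholog_utr)),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  wpos <- 0
  last_aligned <- 0
  for (k in seq_along(pat)) {
    if (pat[k] != "-") wpos <- wpos + 1
    if (pat[k] != "-" && sub[k] != "-") last_aligned <- wpos
  }
  trimmed <- substr(window, 1, last_aligned)
  tibble(sequence = trimmed, length = nchar(trimmed),
         provenance = "ortholog_trimmed")
}

#' Predict miRNA targets by site accessibility
#'
#' For every miRNA-UTR pair, finds seed sites, scores each as
#' `ddG = dG_duplex - dG_open`, keeps the best (most negative) site per
#' pair, and retains pairs with `ddG <= cutoff` (inclusive).
#'
#' @param mirnas Tibble (`mirna_id`, `sequence`) of mature miRNAs.
#' @param utrs Tibble (`gene_id`, `sequence`) of 3'UTR records.
#' @param cutoff Retention cutoff on ddG (kcal/mol).
#' @param model An [energy_model()].
#' @param flank_5p Extra UTR bases 5' of the seed region included in the
#'   duplex context (pairing the miRNA 3' end).
#' @param window Accessibility window (nt).
#' @param allow_6mer Passed to [find_seed_sites()].
#' @return Tibble of all best-per-pair sites: `gene_id`, `mirna_id`,
#'   `site_start`, `site_end`, `seed_class`, `dG_duplex`, `dG_open`, `ddG`,
#'   `retained`.
#' @export
predict_targets <- function(mirnas, utrs, cutoff = -10,
                            model = energy_model(), flank_5p = 15,
                            window = 70, allow_6mer = FALSE) {
  out <- list()
  for (g in seq_len(nrow(utrs))) {
    utr <- utrs$sequence[g]
    for (m in seq_len(nrow(mirnas))) {
      sites <- find_seed_sites(mirnas$sequence[m], utr, allow_6mer = allow_6mer)
      if (nrow(sites) == 0) next
      sites$dG_duplex <- NA_real_
      sites$dG_open <- NA_real_
      for (s in seq_len(nrow(sites))) {
        ctx_start <- max(1, sites$site_start[s] - flank_5p)
        ctx <- substr(utr, ctx_start, sites$site_end[s])
        sites$dG_duplex[s] <- duplex_energy(mirnas$sequence[m], ctx, model)
        sites$dG_open[s] <- open_energy(utr, sites$site_start[s],
                                        sites$site_end[s], window = window)
      }
      sites$ddG <- sites$dG_duplex - sites$dG_open
      best <- sites[which.min(sites$ddG), , drop = FALSE]
      best$gene_id <- utrs$gene_id[g]
      best$mirna_id <- mirnas$mirna_id[m]
      out[[length(out) + 1]] <- best
    }
  }
  if (!length(out)) {
    return(tibble(gene_id = character(0), mirna_id = character(0),
                  site_start = integer(0), site_end = integer(0),
                  seed_class = character(0), dG_duplex = numeric(0),
                  dG_open = numeric(0), ddG = numeric(0),
                  retained = logical(0)))
  }
  res <- bind_rows(out)
  res$retained <- res$ddG <= cutoff
  res[, c("gene_id", "mirna_id", "site_start", "site_end", "seed_class",
          "dG_duplex", "dG_open", "ddG", "retained")]
}
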
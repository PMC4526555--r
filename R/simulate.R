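#' Simulation configuration
#'
#' Parameters controlling the synthetic small-RNA study. The defaults emulate
#' a four-library 2-tissue (brain, white adipose tissue) x 2-state
#' (hibernating, active) design: a random genome carrying planted hairpin
#' precursors of roughly 90 nt (stem + terminal loop), decoy non-coding RNA
#' and repeat-element intervals, and read libraries of 18-33 nt inserts with
#' a +/-2 nt cleavage offset at each mature end and heavy read duplication.
#'
#' @param genome_length Genome length in nt.
#' @param gc_content GC fraction of the background genome, in (0, 1).
#' @param n_hairpins Number of planted miRNA precursors.
#' @param precursor_length_mean Nominal mean precursor length (nt); the stem
#'   and loop ranges below are chosen so `2 * stem + loop` centres here.
#' @param stem_length Integer range (min, max) of perfect stem length in bp.
#' @param loop_length Integer range (min, max) of terminal loop length in nt.
#' @param mature_length Integer range of mature miRNA length in nt.
#' @param conserved_fraction Fraction of planted precursors whose matures are
#'   emitted in the known-miRNA set (the "conserved" ones).
#' @param n_ncrna_decoys Number of decoy ncRNA intervals.
#' @param n_repeat_elements Named integer vector of decoy repeat counts per
#'   class (LINE, SINE, LTR, DNA, SSR, Low).
#' @param read_length_range Insert length range (nt) for decoy/background
#'   reads; also the retention bounds used downstream.
#' @param adapter_sequence 3' sequencing adapter appended to short inserts.
#' @param read_cycle Number of sequencing cycles; inserts shorter than this
#'   are padded with adapter sequence.
#' @param library_depth Reads per library.
#' @param mature_fraction,decoy_fraction Expected fractions of distinct read
#'   templates drawn from mature arms and from decoy annotations; the
#'   remainder is uniform genomic background.
#' @param offset_probs Probability vector over 5'/3'-end offsets -2..+2.
#' @param duplication_factor Mean copies per distinct read template.
#' @param min_feature_gap Minimum spacing (nt) between planted features.
#' @param seed Integer seed; identical configurations and seeds give
#'   byte-identical outputs.
#' @return A validated list of class `tormir_sim_config`.
#' @export
sim_config <- function(genome_length = 100000,
                       gc_content = 0.42,
                       n_hairpins = 30,
                       precursor_length_mean = 90,
                       stem_length = c(35, 42),
                       loop_length = c(8, 14),
                       mature_length = c(20, 23),
                       conserved_fraction = 0.5,
                       n_ncrna_decoys = 20,
                       n_repeat_elements = c(LINE = 3, SINE = 4, LTR = 2,
                                             DNA = 2, SSR = 2, Low = 2),
                       read_length_range = c(18, 33),
                       adapter_sequence = "TGGAATTCTCGGGTGCCAAGG",
                       read_cycle = 36,
                       library_depth = 10000,
                       mature_fraction = 0.5,
                       decoy_fraction = 0.2,
                       offset_probs = c(0.05, 0.2, 0.5, 0.2, 0.05),
                       duplication_factor = 5,
                       min_feature_gap = 400,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_content = gc_content, n_hairpins = as.integer(n_hairpins),
              precursor_length_mean = precursor_length_mean,
              stem_length = as.integer(stem_length),
              loop_length = as.integer(loop_length),
              mature_length = as.integer(mature_length),
              conserved_fraction = conserved_fraction,
              n_ncrna_decoys = as.integer(n_ncrna_decoys),
              n_repeat_elements = n_repeat_elements,
              read_length_range = as.integer(read_length_range),
              adapter_sequence = toupper(adapter_sequence),
              read_cycle = as.integer(read_cycle),
              library_depth = as.integer(library_depth),
              mature_fraction = mature_fraction,
              decoy_fraction = decoy_fraction,
              offset_probs = offset_probs,
              duplication_factor = duplication_factor,
              min_feature_gap = as.integer(min_feature_gap),
              seed = as.integer(seed))
  stopifnot(cfg$genome_length > 0, cfg$n_hairpins >= 0,
            all(cfg$stem_length > 0), all(cfg$loop_length > 0),
            cfg$library_depth >= 0, cfg$duplication_factor >= 1)
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1) {
    abort("gc_content must lie in (0, 1)")
  }
  if (length(cfg$offset_probs) != 5 ||
      abs(sum(cfg$offset_probs) - 1) > 1e-8 || any(cfg$offset_probs < 0)) {
    abort("offset_probs must be 5 non-negative values summing to 1")
  }
  if (cfg$mature_fraction + cfg$decoy_fraction > 1) {
    abort("mature_fraction + decoy_fraction must be <= 1")
  }
  structure(cfg, class = "tormir_sim_config")
}

# sample a precursor whose fold reproduces the designed stem exactly and
# which passes the hairpin criteria used by the discovery module
sample_precursor <- function(cfg) {
  for (try in seq_len(200)) {
    S <- sample(seq(cfg$stem_length[1], cfg$stem_length[2]), 1)
    l <- sample(seq(cfg$loop_length[1], cfg$loop_length[2]), 1)
    m <- sample(seq(cfg$mature_length[1], cfg$mature_length[2]), 1)
    arm <- random_dna(S, cfg$gc_content)
    loop <- random_dna(l, cfg$gc_content)
    seq <- paste0(arm, loop, revcomp(arm))
    P <- nchar(seq)
    fd <- fold_rna(seq)
    stem_ok <- all(fd$pairing[1:S] == P + 1 - (1:S))
    if (!stem_ok) next
    m5 <- c(1L, m)
    m3 <- c(P - m + 1L, P)
    if (!check_hairpin(fd, m5)$pass) next
    if (!check_hairpin(fd, m3)$pass) next
    return(list(sequence = seq, stem = S, loop = l,
                mature5p = m5, mature3p = m3))
  }
  abort("could not sample a canonical precursor; widen stem/loop ranges")
}

place_features <- function(lengths, genome_length, gap, max_tries = 5000) {
  starts <- integer(0)
  ends <- integer(0)
  for (len in lengths) {
    if (genome_length - len - 2 * gap <= 0) {
      abort("genome too short to place all features without overlap")
    }
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(genome_length - len - 2 * gap, 1) + gap
      ok <- !length(starts) || all(s >= ends + gap | s + len + gap <= starts)
      if (ok) {
        starts <- c(starts, s)
        ends <- c(ends, s + len)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("genome too short to place all features without overlap")
    }
  }
  tibble(start = starts, end = ends)
}

#' Simulate a genome with planted miRNA precursors and decoy annotations
#'
#' Builds a random genome, plants `n_hairpins` precursors (perfect inverted
#' stems with a terminal loop, re-folded at construction so that each passes
#' the discovery module's hairpin criteria), and scatters decoy ncRNA and
#' repeat-element intervals. Coordinates are 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return A list of class `tormir_simulation`: `genome` (a
#'   [Biostrings::DNAStringSet]), `truth` (planted precursor records),
#'   `ncrna` and `repeats` (decoy annotation tracks), `known_mature`
#'   (the conserved mature set), and the `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  contig <- "contig1"

  precursors <- lapply(seq_len(cfg$n_hairpins), function(i) sample_precursor(cfg))
  nc_sub <- c("rRNA", "tRNA", "snoRNA", "snRNA", "other_ncRNA")
  nc_lens <- if (cfg$n_ncrna_decoys > 0) sample(70:150, cfg$n_ncrna_decoys, TRUE) else integer(0)
  rep_classes <- rep(names(cfg$n_repeat_elements), cfg$n_repeat_elements)
  rep_lens <- vapply(rep_classes, function(cl) {
    switch(cl, LINE = sample(400:700, 1), SINE = sample(150:300, 1),
           LTR = sample(200:400, 1), DNA = sample(100:300, 1),
           SSR = sample(60:120, 1), Low = sample(60:150, 1))
  }, integer(1))

  lens <- c(vapply(precursors, function(p) nchar(p$sequence), integer(1)),
            nc_lens, rep_lens)
  loci <- place_features(lens, cfg$genome_length, cfg$min_feature_gap)

  genome <- random_dna(cfg$genome_length, cfg$gc_content)
  n_p <- cfg$n_hairpins
  n_nc <- cfg$n_ncrna_decoys

  strands <- if (n_p > 0) sample(c("+", "-"), n_p, TRUE) else character(0)
  truth <- tibble(
    feature_id = sprintf("hairpin-%02d", seq_len(n_p)),
    class = rep("miRNA_hairpin", n_p),
    contig = rep(contig, n_p),
    start = loci$start[seq_len(n_p)],
    end = loci$end[seq_len(n_p)],
    strand = strands,
    sequence = vapply(precursors, `[[`, "", "sequence"),
    stem = vapply(precursors, function(p) p$stem, integer(1)),
    mature5p_start = vapply(precursors, function(p) p$mature5p[1], integer(1)),
    mature5p_end = vapply(precursors, function(p) p$mature5p[2], integer(1)),
    mature3p_start = vapply(precursors, function(p) p$mature3p[1], integer(1)),
    mature3p_end = vapply(precursors, function(p) p$mature3p[2], integer(1)),
    is_conserved = if (n_p > 0) {
      seq_len(n_p) <= round(n_p * cfg$conserved_fraction)
    } else logical(0)
  )
  truth$mature5p_seq <- substr(truth$sequence, truth$mature5p_start, truth$mature5p_end)
  truth$mature3p_seq <- substr(truth$sequence, truth$mature3p_start, truth$mature3p_end)

  nc_idx <- n_p + seq_len(n_nc)
  ncrna <- tibble(
    feature_id = sprintf("ncrna-%02d", seq_len(n_nc)),
    contig = rep(contig, n_nc),
    start = loci$start[nc_idx], end = loci$end[nc_idx],
    subclass = if (n_nc > 0) sample(nc_sub, n_nc, TRUE,
                                    prob = c(0.45, 0.25, 0.15, 0.05, 0.1)) else character(0)
  )
  rp_idx <- n_p + n_nc + seq_along(rep_classes)
  repeats <- tibble(
    feature_id = sprintf("repeat-%02d", seq_along(rep_classes)),
    contig = rep(contig, length(rep_classes)),
    start = loci$start[rp_idx], end = loci$end[rp_idx],
    class = rep_classes
  )

  # splice planted sequences into the background genome
  for (i in seq_len(n_p)) {
    ins <- if (strands[i] == "+") truth$sequence[i] else revcomp(truth$sequence[i])
    substr(genome, truth$start[i] + 1, truth$end[i]) <- ins
  }
  # SSR decoys get genuine tandem repeats; others keep background sequence
  for (i in seq_along(rep_classes)) {
    if (rep_classes[i] == "SSR") {
      unit <- random_dna(sample(2:6, 1), cfg$gc_content)
      len <- repeats$end[i] - repeats$start[i]
      substr(genome, repeats$start[i] + 1, repeats$end[i]) <-
        substr(strrep(unit, ceiling(len / nchar(unit))), 1, len)
    }
  }
  ncrna$sequence <- if (nrow(ncrna)) {
    substring(genome, ncrna$start + 1, ncrna$end)
  } else character(0)
  repeats$sequence <- if (nrow(repeats)) {
    substring(genome, repeats$start + 1, repeats$end)
  } else character(0)

  conserved <- truth[truth$is_conserved, , drop = FALSE]
  known_mature <- tibble(
    mirna_id = c(sprintf("con-mir-%02d-5p", which(truth$is_conserved)),
                 sprintf("con-mir-%02d-3p", which(truth$is_conserved))),
    sequence = c(conserved$mature5p_seq, conserved$mature3p_seq)
  )

  structure(list(genome = Biostrings::DNAStringSet(setNames(genome, contig)),
                 truth = truth, ncrna = ncrna, repeats = repeats,
                 known_mature = known_mature, config = cfg),
            class = "tormir_simulation")
}

# precursor-relative span -> genomic 0-based half-open interval
precursor_span_to_genomic <- function(start0, P, strand, s, e) {
  if (strand == "+") c(start0 + s - 1L, start0 + e)
  else c(start0 + P - e, start0 + P - s + 1L)
}

#' Simulate a small-RNA read library
#'
#' Draws distinct read templates from planted mature arms (with independent
#' 5' and 3' end offsets), decoy annotations and uniform genomic background,
#' then duplicates them to the requested depth. Inserts shorter than the
#' sequencing cycle are padded with adapter sequence, as on the instrument.
#'
#' @param sim A `tormir_simulation` from [simulate_genome()].
#' @param library_label Library name, e.g. `"HB"`.
#' @param depth Number of reads; defaults to the configured `library_depth`.
#' @param seed Optional seed for standalone calls; when `NULL` the current
#'   RNG stream is used (one stream per run).
#' @return A tibble with one row per read: `read_id`, `library`, `sequence`
#'   (raw, adapter-padded), `quality`, `insert`, `origin`
#'   (mature/decoy/background), `feature_id`, `contig`, `start`, `end`,
#'   `strand` (the recorded true origin).
#' @export
simulate_reads <- function(sim, library_label, depth = NULL, seed = NULL) {
  cfg <- sim$config
  if (!is.null(seed)) set.seed(seed)
  depth <- depth %||% cfg$library_depth
  empty <- tibble(read_id = character(0), library = character(0),
                  sequence = character(0), quality = character(0),
                  insert = character(0), origin = character(0),
                  feature_id = character(0), contig = character(0),
                  start = integer(0), end = integer(0), strand = character(0))
  if (depth == 0) return(empty)

  genome <- as.character(sim$genome[[1]])
  contig <- names(sim$genome)[1]
  glen <- nchar(genome)
  decoys <- bind_rows(
    sim$ncrna[, c("feature_id", "start", "end")],
    sim$repeats[, c("feature_id", "start", "end")]
  )
  p_mat <- if (nrow(sim$truth) > 0) cfg$mature_fraction else 0
  p_dec <- if (nrow(decoys) > 0) cfg$decoy_fraction else 0

  n_templates <- max(1L, as.integer(round(depth / cfg$duplication_factor)))
  cat_draw <- sample(c("mature", "decoy", "background"), n_templates,
                     replace = TRUE, prob = c(p_mat, p_dec, 1 - p_mat - p_dec))
  offs <- -2:2

  one_template <- function(category) {
    if (category == "mature") {
      i <- sample.int(nrow(sim$truth), 1)
      tr <- sim$truth[i, ]
      arm <- sample(c("5p", "3p"), 1)
      sp <- if (arm == "5p") c(tr$mature5p_start, tr$mature5p_end)
            else c(tr$mature3p_start, tr$mature3p_end)
      P <- nchar(tr$sequence)
      s <- max(1L, sp[1] + sample(offs, 1, prob = cfg$offset_probs))
      e <- min(P, sp[2] + sample(offs, 1, prob = cfg$offset_probs))
      g <- precursor_span_to_genomic(tr$start, P, tr$strand, s, e)
      ins <- substr(genome, g[1] + 1, g[2])
      if (tr$strand == "-") ins <- revcomp(ins)
      list(insert = ins, origin = "mature", feature_id = tr$feature_id,
           start = g[1], end = g[2], strand = tr$strand)
    } else if (category == "decoy") {
      i <- sample.int(nrow(decoys), 1)
      d <- decoys[i, ]
      len <- sample(seq(cfg$read_length_range[1], cfg$read_length_range[2]), 1)
      len <- min(len, d$end - d$start)
      s <- d$start + sample.int(d$end - d$start - len + 1L, 1) - 1L
      list(insert = substr(genome, s + 1, s + len), origin = "decoy",
           feature_id = d$feature_id, start = s, end = s + len, strand = "+")
    } else {
      len <- sample(seq(cfg$read_length_range[1], cfg$read_length_range[2]), 1)
      s <- sample.int(glen - len, 1)
      strand <- sample(c("+", "-"), 1)
      ins <- substr(genome, s + 1, s + len)
      if (strand == "-") ins <- revcomp(ins)
      list(insert = ins, origin = "background", feature_id = NA_character_,
           start = s, end = s + len, strand = strand)
    }
  }

  tmpl <- map(cat_draw, one_template)
  templates <- tibble(
    insert = map_chr(tmpl, "insert"), origin = map_chr(tmpl, "origin"),
    feature_id = map_chr(tmpl, "feature_id"),
    contig = contig,
    start = map_int(tmpl, function(x) as.integer(x$start)),
    end = map_int(tmpl, function(x) as.integer(x$end)),
    strand = map_chr(tmpl, "strand")
  )
  copies <- as.vector(rmultinom(1, depth, rep(1, n_templates)))
  reads <- templates[rep(seq_len(n_templates), copies), ]
  pad <- pmax(0L, cfg$read_cycle - nchar(reads$insert))
  adapter_fill <- substr(strrep(cfg$adapter_sequence,
                                ceiling(cfg$read_cycle / nchar(cfg$adapter_sequence))),
                         1, max(pad))
  reads$sequence <- paste0(reads$insert, substring(adapter_fill, 1, pad))
  reads$quality <- strrep("I", nchar(reads$sequence))
  reads$read_id <- sprintf("%s_r%06d", library_label, seq_len(nrow(reads)))
  reads$library <- library_label
  reads[, c("read_id", "library", "sequence", "quality", "insert", "origin",
            "feature_id", "contig", "start", "end", "strand")]
}

#' Count-matrix simulation specification
#'
#' @param n_features Number of mature miRNA features.
#' @param baseline_mean Baseline negative-binomial mean count per library.
#' @param dispersion NB dispersion phi (variance = mu + phi * mu^2);
#'   `0` gives Poisson counts.
#' @param de_fraction Fraction of features that are differentially expressed.
#' @param de_logfc Planted log2 fold-change magnitude applied to the
#'   hibernating library of the feature's designated tissue.
#' @param seed Integer seed.
#' @return A list of class `tormir_count_sim_spec`.
#' @export
count_sim_spec <- function(n_features = 1000, baseline_mean = 100,
                           dispersion = 0.1, de_fraction = 0.1,
                           de_logfc = 2, seed = 1L) {
  stopifnot(n_features >= 0, baseline_mean > 0, dispersion >= 0,
            de_fraction >= 0, de_fraction <= 1)
  structure(list(n_features = as.integer(n_features),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 de_fraction = de_fraction, de_logfc = de_logfc,
                 seed = as.integer(seed)),
            class = "tormir_count_sim_spec")
}

#' Simulate a four-library negative-binomial count matrix with planted truth
#'
#' Features are i.i.d. NB with the configured mean and dispersion in all four
#' libraries (HB, AB, HA, AA); differentially expressed features have their
#' mean multiplied by `2^(sign * de_logfc)` in the hibernating library of a
#' randomly designated tissue.
#'
#' @param spec A [count_sim_spec()].
#' @return A list of class `tormir_count_sim` with `counts` (tibble,
#'   feature x HB/AB/HA/AA) and `truth` (per-feature DE status, tissue,
#'   direction and true log2 fold change).
#' @export
simulate_counts <- function(spec = count_sim_spec()) {
  set.seed(spec$seed)
  n <- spec$n_features
  libs <- c("HB", "AB", "HA", "AA")
  n_de <- round(n * spec$de_fraction)
  is_de <- seq_len(n) <= n_de
  tissue <- rep(NA_character_, n)
  sign <- rep(0L, n)
  if (n_de > 0) {
    tissue[is_de] <- sample(c("brain", "WAT"), n_de, TRUE)
    sign[is_de] <- sample(c(-1L, 1L), n_de, TRUE)
  }
  mu <- matrix(spec$baseline_mean, nrow = n, ncol = 4,
               dimnames = list(NULL, libs))
  hib_col <- ifelse(tissue == "brain", "HB", "HA")
  for (i in which(is_de)) {
    mu[i, hib_col[i]] <- mu[i, hib_col[i]] * 2^(sign[i] * spec$de_logfc)
  }
  draw <- function(m) {
    if (spec$dispersion == 0) rpois(n, m)
    else rnbinom(n, size = 1 / spec$dispersion, mu = m)
  }
  counts <- tibble(feature_id = sprintf("feature-%04d", seq_len(n)))
  for (l in libs) counts[[l]] <- draw(mu[, l])
  truth <- tibble(feature_id = counts$feature_id, is_de = is_de,
                  tissue = tissue, direction = sign,
                  true_logfc = sign * spec$de_logfc)
  structure(list(counts = counts, truth = truth, spec = spec),
            class = "tormir_count_sim")
}
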
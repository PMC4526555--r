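#' Quantify mature miRNA expression per library
#'
#' A unique read contributes its per-library counts to a mature feature when
#' one of its genomic hit intervals lies within the mature interval extended
#' by `slack` nt at each end (the same +/-2 nt window used for mature
#' calling). Reads compatible with several features contribute to each and
#' are flagged ambiguous.
#'
#' @param collapsed Unique reads with per-library count columns.
#' @param hits Genome hits for those reads.
#' @param matures Tibble of mature features: `mirna_id`, `contig`, `start`,
#'   `end` (0-based half-open).
#' @param libraries Library column names; default all count columns.
#' @param slack Window extension (nt).
#' @return Tibble `mirna_id` x library counts, with an `ambiguous_reads`
#'   attribute listing multi-feature reads.
#' @export
quantify_mature <- function(collapsed, hits, matures, libraries = NULL,
                            slack = 2) {
  libraries <- libraries %||%
    setdiff(names(collapsed), c("sequence", "class", "total", "n_loci"))
  assign <- inner_join(hits, matures, by = "contig",
                       relationship = "many-to-many",
                       suffix = c("", ".m")) |>
    filter(.data$start >= .data$start.m - slack,
           .data$end <= .data$end.m + slack) |>
    distinct(.data$sequence, .data$mirna_id)
  multi <- assign |> count(.data$sequence) |> filter(.data$n > 1)
  joined <- inner_join(assign, collapsed, by = "sequence")
  out <- joined |>
    group_by(.data$mirna_id) |>
    summarise(across(all_of(libraries), sum), .groups = "drop")
  missing <- setdiff(matures$mirna_id, out$mirna_id)
  if (length(missing)) {
    zero <- tibble(mirna_id = missing)
    for (l in libraries) zero[[l]] <- 0L
    out <- bind_rows(out, zero)
  }
  out <- arrange(out, .data$mirna_id)
  attr(out, "ambiguous_reads") <- multi$sequence
  out
}

#' Transcripts-per-million normalisation
#'
#' `tpm = count / library_total * 1e6`. Library totals are all mapped
#' small-RNA reads, so column sums are at most 1e6 with equality when the
#' features account for every mapped read.
#'
#' @param counts Tibble with a feature id column and numeric library columns.
#' @param totals Named numeric vector of per-library totals.
#' @return The tibble with counts replaced by TPM.
#' @export
tpm <- function(counts, totals) {
  if (any(totals <= 0)) abort("library totals must be positive")
  libs <- intersect(names(counts), names(totals))
  if (!length(libs)) abort("no library columns match the totals")
  for (l in libs) counts[[l]] <- counts[[l]] / totals[[l]] * 1e6
  counts
}

#' @rdname tpm
#' @param pseudocount Added before taking log2.
#' @export
log_tpm <- function(counts, totals, pseudocount = 1) {
  x <- tpm(counts, totals)
  libs <- intersect(names(x), names(totals))
  for (l in libs) x[[l]] <- log2(x[[l]] + pseudocount)
  x
}

# conditional probabilities of k successes given total s for two i.i.d.
# NB(mu, phi) counts; independent of mu, negative-hypergeometric weights
nb_conditional <- function(s, phi) {
  k <- 0:s
  if (phi <= 0) {
    lw <- dbinom(k, s, 0.5, log = TRUE)
  } else {
    r <- 1 / phi
    lw <- lchoose(k + r - 1, k) + lchoose(s - k + r - 1, s - k)
  }
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Exact negative-binomial test for two pooled libraries
#'
#' Conditional two-sided exact test for a difference in expression between
#' one hibernating and one active library with no replicates. Counts are
#' first scaled to the geometric mean of the two library totals (rounded);
#' the test then conditions on the scaled sum `s` and sums the conditional
#' probabilities of all outcomes no more probable than the observed one.
#' With `dispersion = 0` this is an exact binomial test with success
#' probability `total_h / (total_h + total_a)` on the raw counts. A feature
#' with zero counts in both libraries returns p = 1.
#'
#' @param count_h,count_a Counts in the hibernating and active library
#'   (vectorised).
#' @param total_h,total_a Library totals (all mapped small-RNA reads).
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); a
#'   configuration input since pooled libraries carry no replicate
#'   information to estimate it from.
#' @return Two-sided p-value(s).
#' @export
#' @examples
#' exact_nb_test(5, 0, 1e6, 1e6, dispersion = 0) # 0.0625
#' exact_nb_test(0, 0, 1e6, 1e6)                 # 1
exact_nb_test <- function(count_h, count_a, total_h, total_a,
                          dispersion = 0.1) {
  if (any(c(count_h, count_a) < 0) || any(c(total_h, total_a) <= 0)) {
    abort("counts must be non-negative and totals positive")
  }
  if (dispersion < 0) abort("dispersion must be >= 0")
  one <- function(yh, ya) {
    if (yh == 0 && ya == 0) return(1)
    if (dispersion <= 0) {
      p0 <- total_h / (total_h + total_a)
      s <- yh + ya
      w <- dbinom(0:s, s, p0)
      obs <- w[yh + 1]
    } else {
      N <- sqrt(total_h * total_a)
      y1 <- round(yh * N / total_h)
      y2 <- round(ya * N / total_a)
      s <- y1 + y2
      w <- nb_conditional(s, dispersion)
      obs <- w[y1 + 1]
    }
    min(1, sum(w[w <= obs * (1 + 1e-10)]))
  }
  mapply(one, count_h, count_a)
}

#' Moderated log2 fold change
#'
#' `log2((count_h + prior) / total_h) - log2((count_a + prior) / total_a)`;
#' the prior count keeps fold changes finite for one-sided expression.
#'
#' @inheritParams exact_nb_test
#' @param prior Prior count added per library.
#' @return log2 fold change (hibernating over active), vectorised.
#' @export
log_fc <- function(count_h, count_a, total_h, total_a, prior = 0.5) {
  log2((count_h + prior) / total_h) - log2((count_a + prior) / total_a)
}

#' Differential expression over the four-library design
#'
#' Runs the exact NB test and moderated log fold change for each comparison
#' (brain: HB vs AB; white adipose: HA vs AA by default). `logTPM` is
#' log2(mean TPM + 1) over the two libraries compared. Direction is UP/DOWN
#' by fold-change sign, or `"absent"` when both counts are zero.
#'
#' @param counts Tibble: `feature_id` (or `mirna_id`) plus library count
#'   columns.
#' @param totals Named per-library totals; defaults to column sums.
#' @param comparisons Named list of `c(hibernating, active)` column pairs.
#' @param dispersion NB dispersion.
#' @param p_max,min_abs_lfc Significance thresholds (inclusive).
#' @param prior Prior count for [log_fc()].
#' @return A tibble of class `tormir_de`: one row per feature and
#'   comparison with `logFC`, `logTPM`, `p_value`, `direction`,
#'   `significant`.
#' @export
test_de <- function(counts, totals = NULL,
                    comparisons = list(HB_vs_AB = c("HB", "AB"),
                                       HA_vs_AA = c("HA", "AA")),
                    dispersion = 0.1, p_max = 0.01, min_abs_lfc = 1,
                    prior = 0.5) {
  id_col <- intersect(c("feature_id", "mirna_id"), names(counts))[1]
  if (is.na(id_col)) abort("counts needs a feature_id or mirna_id column")
  libs <- unique(unlist(comparisons))
  totals <- totals %||% vapply(counts[libs], sum, numeric(1))
  out <- list()
  for (cmp in names(comparisons)) {
    h <- comparisons[[cmp]][1]
    a <- comparisons[[cmp]][2]
    yh <- counts[[h]]
    ya <- counts[[a]]
    lfc <- log_fc(yh, ya, totals[[h]], totals[[a]], prior = prior)
    p <- exact_nb_test(yh, ya, totals[[h]], totals[[a]],
                       dispersion = dispersion)
    absent <- yh == 0 & ya == 0
    lfc[absent] <- 0
    tpm_h <- yh / totals[[h]] * 1e6
    tpm_a <- ya / totals[[a]] * 1e6
    out[[cmp]] <- tibble(
      feature_id = counts[[id_col]], comparison = cmp,
      count_h = yh, count_a = ya,
      logFC = lfc, logTPM = log2((tpm_h + tpm_a) / 2 + 1), p_value = p,
      direction = dplyr::case_when(absent ~ "absent", lfc > 0 ~ "UP",
                                   lfc < 0 ~ "DOWN", TRUE ~ "UP"),
      significant = !absent & p <= p_max & abs(lfc) >= min_abs_lfc)
  }
  res <- bind_rows(out)
  class(res) <- c("tormir_de", class(res))
  attr(res, "thresholds") <- c(p_max = p_max, min_abs_lfc = min_abs_lfc)
  attr(res, "dispersion") <- dispersion
  res
}

#' Call the significant set at inclusive thresholds
#'
#' @param de A `tormir_de` tibble from [test_de()].
#' @param p_max,min_abs_lfc Inclusive thresholds on p and |logFC|.
#' @return The significant subset; `attr(, "shared")` lists features
#'   significant in every comparison.
#' @export
call_de <- function(de, p_max = 0.01, min_abs_lfc = 1) {
  sig <- de[de$direction != "absent" & de$p_value <= p_max &
              abs(de$logFC) >= min_abs_lfc, , drop = FALSE]
  per_cmp <- split(sig$feature_id, sig$comparison)
  attr(sig, "shared") <- Reduce(intersect, per_cmp %||% list(character(0)))
  sig
}

#' Tissue- and state-specificity calls
#'
#' A feature is tissue-specific when both libraries of the other tissue have
#' zero counts, and state-specific when both libraries of the other state
#' do. `high_count` flags totals above 100. Features with no counts at all
#' are marked `not_detected`.
#'
#' @param counts Tibble with `HB`, `AB`, `HA`, `AA` columns.
#' @return Tibble: feature id, `pattern`, `high_count`.
#' @export
call_specific <- function(counts) {
  id_col <- intersect(c("feature_id", "mirna_id"), names(counts))[1]
  brain <- counts$HB + counts$AB
  wat <- counts$HA + counts$AA
  hib <- counts$HB + counts$HA
  act <- counts$AB + counts$AA
  total <- brain + wat
  pattern <- dplyr::case_when(
    total == 0 ~ "not_detected",
    wat == 0 ~ "tissue_specific_brain",
    brain == 0 ~ "tissue_specific_WAT",
    act == 0 | hib == 0 ~ "state_specific",
    TRUE ~ "ubiquitous")
  tibble(feature_id = counts[[id_col]], pattern = pattern,
         high_count = total > 100)
}

#' @method tidy tormir_de
#' @export
tidy.tormir_de <- function(x, ...) {
  as_tibble(x)
}

#' @method glance tormir_de
#' @export
glance.tormir_de <- function(x, ...) {
  th <- attr(x, "thresholds")
  x |>
    group_by(.data$comparison) |>
    summarise(n_features = n(),
              n_absent = sum(.data$direction == "absent"),
              n_significant = sum(.data$significant),
              n_up = sum(.data$significant & .data$direction == "UP"),
              n_down = sum(.data$significant & .data$direction == "DOWN"),
              .groups = "drop") |>
    mutate(p_max = th[["p_max"]], min_abs_lfc = th[["min_abs_lfc"]])
}
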
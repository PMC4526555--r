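#' Hypergeometric enrichment over an annotation map
#'
#' Upper-tail hypergeometric test per category (pathway or GO term) with
#' Benjamini-Hochberg adjustment across categories. Query genes outside the
#' universe are dropped with a warning.
#'
#' @param query Character vector of gene ids (e.g. predicted targets of the
#'   differentially expressed miRNAs).
#' @param annotation Tibble with `category` and `gene` columns.
#' @param universe Optional character vector; defaults to all annotated
#'   genes.
#' @return Tibble sorted by p: `category`, `overlap`, `category_size`,
#'   `query_size`, `universe_size`, `p_value`, `p_adjust`.
#' @export
enrich_hypergeom <- function(query, annotation, universe = NULL) {
  universe <- unique(universe %||% annotation$gene)
  if (!length(universe)) abort("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query genes outside the universe dropped",
                 length(outside)))
  }
  q <- unique(intersect(query, universe))
  N <- length(universe)
  n <- length(q)
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  res <- annotation |>
    group_by(.data$category) |>
    summarise(category_size = dplyr::n_distinct(.data$gene),
              overlap = sum(unique(.data$gene) %in% q), .groups = "drop") |>
    mutate(query_size = n, universe_size = N,
           p_value = phyper(.data$overlap - 1, .data$category_size,
                            N - .data$category_size, n, lower.tail = FALSE),
           p_adjust = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value)
  res[, c("category", "overlap", "category_size", "query_size",
          "universe_size", "p_value", "p_adjust")]
}

#' Per-category activity comparison between physiological states
#'
#' Two-sided pooled-variance two-sample t-test per category comparing
#' member-gene expression scores between hibernating and active states.
#' Categories with fewer than two scores in either group are skipped with a
#' warning. A zero pooled variance with unequal means is reported as p = 0
#' (t infinite) rather than an error.
#'
#' @param scores Tibble with `category`, `state` (two levels) and `value`.
#' @param case,control The state labels compared (case minus control).
#' @return Tibble: `category`, `n_case`, `n_control`, `t`, `p_value`.
#' @export
activity_ttest <- function(scores, case = "hibernating", control = "active") {
  cats <- unique(scores$category)
  out <- list()
  skipped <- character(0)
  for (cat in cats) {
    x <- scores$value[scores$category == cat & scores$state == case]
    y <- scores$value[scores$category == cat & scores$state == control]
    if (length(x) < 2 || length(y) < 2) {
      skipped <- c(skipped, cat)
      next
    }
    df <- length(x) + length(y) - 2
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
    se <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    if (se == 0) {
      tt <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
      p <- if (tt == 0) 1 else 0
    } else {
      tt <- (mean(x) - mean(y)) / se
      p <- 2 * pt(-abs(tt), df)
    }
    out[[length(out) + 1]] <- tibble(category = cat, n_case = length(x),
                                     n_control = length(y), t = tt,
                                     p_value = p)
  }
  if (length(skipped)) {
    warn(sprintf("skipped %d categories with fewer than 2 scores per group",
                 length(skipped)))
  }
  if (!length(out)) {
    return(tibble(category = character(0), n_case = integer(0),
                  n_control = integer(0), t = numeric(0),
                  p_value = numeric(0)))
  }
  bind_rows(out)
}

#' Link differentially expressed miRNAs to their differentially expressed
#' target mRNAs
#'
#' Emits one link per predicted (retained) miRNA-target pair for which the
#' gene appears in the mRNA table of the matching tissue; the link is
#' flagged `both_significant` when miRNA and mRNA both reach `p_max` in the
#' same tissue comparison. Anti-correlation of directions is annotated, not
#' required.
#'
#' @param de_mirna A `tormir_de` tibble ([test_de()] output).
#' @param de_mrna Tibble: `gene_id`, `tissue`, `logFC`, `p_value`.
#' @param targets [predict_targets()] output (only retained sites are used).
#' @param tissue_map Named map from comparison to tissue label.
#' @param p_max Significance threshold for both platforms.
#' @return Tibble of links: miRNA, gene, tissue, both directions,
#'   `both_significant`, `anticorrelated`; skipped genes in
#'   `attr(, "skipped_genes")`.
#' @export
link_mirna_mrna <- function(de_mirna, de_mrna, targets,
                            tissue_map = c(HB_vs_AB = "brain",
                                           HA_vs_AA = "WAT"),
                            p_max = 0.01) {
  tg <- targets[targets$retained, c("mirna_id", "gene_id")]
  mi <- as_tibble(de_mirna) |>
    mutate(tissue = tissue_map[.data$comparison]) |>
    select(mirna_id = "feature_id", "tissue", mirna_logFC = "logFC",
           mirna_p = "p_value", mirna_direction = "direction")
  links <- inner_join(tg, mi, by = "mirna_id", relationship = "many-to-many")
  known_genes <- unique(de_mrna$gene_id)
  skipped <- setdiff(unique(links$gene_id), known_genes)
  links <- inner_join(links,
                      select(de_mrna, "gene_id", "tissue",
                             mrna_logFC = "logFC", mrna_p = "p_value"),
                      by = c("gene_id", "tissue")) |>
    mutate(mrna_direction = if_else(.data$mrna_logFC >= 0, "UP", "DOWN"),
           both_significant = .data$mirna_p <= p_max & .data$mrna_p <= p_max,
           anticorrelated = sign(.data$mirna_logFC) * sign(.data$mrna_logFC) < 0)
  attr(links, "skipped_genes") <- skipped
  links
}
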
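#' Relative expression from stem-loop qPCR by the 2^-ddCt method
#'
#' Technical replicates are averaged within each biological sample first;
#' dCt = Ct(target) - Ct(reference) per biological sample; ddCt is the mean
#' dCt difference between case and control groups; fold change = 2^-ddCt.
#' A one-way ANOVA on the per-biological-sample dCt values gives the
#' p-value.
#'
#' @param ct Tibble of Ct records: `target_id`, `sample_id`, `group`,
#'   `tissue`, `ct` (one row per technical replicate).
#' @param target Target id to quantify.
#' @param reference Endogenous control id (e.g. 5S rRNA), required for every
#'   sample.
#' @param case,control Group labels (case relative to control).
#' @return Tibble per tissue: `log2_fold` (= -ddCt), `fold`, `p_value`
#'   (ANOVA), `direction`.
#' @export
qpcr_ddct <- function(ct, target, reference = "5S",
                      case = "hibernating", control = "active") {
  # average technical replicates within each biological sample
  per_sample <- ct |>
    group_by(.data$target_id, .data$sample_id, .data$group, .data$tissue) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  tgt <- per_sample[per_sample$target_id == target, , drop = FALSE]
  ref <- per_sample[per_sample$target_id == reference,
                    c("sample_id", "ct"), drop = FALSE]
  missing_ref <- setdiff(tgt$sample_id, ref$sample_id)
  if (length(missing_ref)) {
    abort(paste0("missing reference Ct for sample(s): ",
                 paste(missing_ref, collapse = ", ")))
  }
  dct <- left_join(tgt, rename(ref, ref_ct = "ct"), by = "sample_id") |>
    mutate(dct = .data$ct - .data$ref_ct)
  out <- list()
  for (tis in unique(dct$tissue)) {
    d <- dct[dct$tissue == tis, ]
    dd <- mean(d$dct[d$group == case]) - mean(d$dct[d$group == control])
    aov_res <- anova_oneway(d$dct, d$group)
    out[[length(out) + 1]] <- tibble(
      target_id = target, tissue = tis, ddct = dd, log2_fold = -dd,
      fold = 2^(-dd), p_value = aov_res$p,
      direction = if (dd < 0) "UP" else if (dd > 0) "DOWN" else "flat")
  }
  bind_rows(out)
}

#' One-way ANOVA
#'
#' Standard one-way analysis of variance on per-biological-sample values.
#' Degenerate cases are guarded: all values equal gives F = 0, p = 1; zero
#' within-group variance with unequal group means gives F = Inf, p = 0.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (>= 2 groups, >= 2
#'   values per group).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3)) # F = 13.5
anova_oneway <- function(values, groups) {
  groups <- as.character(groups)
  ns <- table(groups)
  if (length(ns) < 2 || any(ns < 2)) {
    abort("need at least 2 groups with at least 2 values each")
  }
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- length(ns) - 1
  df2 <- length(values) - length(ns)
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Concordance between sequencing and qPCR calls
#'
#' Per target and tissue, compares the sequencing log fold change and call
#' with the qPCR result: direction concordance (same sign) and significance
#' concordance (both or neither below their thresholds).
#'
#' @param seq_de Tibble: `target_id`, `tissue`, `logFC`, `p_value` from
#'   sequencing.
#' @param qpcr Output rows of [qpcr_ddct()] (possibly several targets bound
#'   together).
#' @param p_max Significance threshold applied to both platforms.
#' @return Tibble per target/tissue with both effect sizes, flags
#'   `direction_concordant` and `significance_concordant`; summary counts in
#'   `attr(, "summary")`.
#' @export
qpcr_concordance <- function(seq_de, qpcr, p_max = 0.01) {
  j <- inner_join(seq_de, qpcr, by = c("target_id", "tissue"),
                  suffix = c("_seq", "_qpcr")) |>
    mutate(direction_concordant = sign(.data$logFC) == sign(.data$log2_fold),
           significance_concordant =
             (.data$p_value_seq <= p_max) == (.data$p_value_qpcr <= p_max))
  attr(j, "summary") <- tibble(
    n = nrow(j),
    n_direction_concordant = sum(j$direction_concordant),
    n_significance_concordant = sum(j$significance_concordant))
  j
}
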
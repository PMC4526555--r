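#' Volcano plot of differential expression results
#'
#' @param object A `tormir_de` tibble from [test_de()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tormir_de
#' @export
autoplot.tormir_de <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[d$direction != "absent", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$logFC,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (hibernating / active)",
                  y = "-log10 p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Read length distribution per library
#'
#' @param clean Tibble of cleaned reads (`sequence`, `library`).
#' @return A ggplot of the 18-33 nt length histogram.
#' @export
plot_length_distribution <- function(clean) {
  h <- length_histogram(clean)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$length, y = .data$n,
                                  fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "read length (nt)", y = "reads") +
    ggplot2::theme_minimal()
}

#' Class composition of mapped reads
#'
#' @param table Output of [classification_table()].
#' @return A ggplot of per-library class proportions of total sequences.
#' @export
plot_classification <- function(table) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$library, y = .data$total_reads,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "share of mapped reads", fill = "class") +
    ggplot2::theme_minimal()
}
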
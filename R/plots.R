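# ggplot2 displays for the main result types.

#' Forest plot of per-SNP additive odds ratios
#'
#' @param object an `assoc_table` from [association_table()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.assoc_table <- function(object, ...) {
  df <- as_tibble(object)
  df$rsid <- factor(df$rsid, levels = rev(df$rsid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$rsid)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio per risk allele (log scale)", y = NULL,
      colour = "Significant"
    ) +
    ggplot2::theme_minimal()
}

#' Per-quartile odds ratios for a GRS partition
#'
#' @param object a `grs_quartiles` object.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.grs_quartiles <- function(object, ...) {
  qa <- quartile_association(object)
  qa$or_plot <- ifelse(qa$reference, 1, qa$or)
  ggplot2::ggplot(qa, ggplot2::aes(x = .data$quartile, y = .data$or_plot)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.15,
      na.rm = TRUE
    ) +
    ggplot2::geom_point(size = 2.5, na.rm = TRUE) +
    ggplot2::labs(
      x = "Weighted GRS quartile", y = "Odds ratio vs lowest quartile"
    ) +
    ggplot2::theme_minimal()
}

#' Pairwise LD heatmap
#'
#' @param pairs a tibble from [ld_pairwise()].
#' @param stat which statistic to shade: `"d_prime"` (default) or `"r2"`.
#' @return a ggplot.
#' @export
plot_ld_heatmap <- function(pairs, stat = c("d_prime", "r2")) {
  stat <- match.arg(stat)
  ids <- unique(c(pairs$rsid_a, pairs$rsid_b))
  df <- pairs
  df$rsid_a <- factor(df$rsid_a, levels = ids)
  df$rsid_b <- factor(df$rsid_b, levels = ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rsid_a, y = .data$rsid_b,
                                   fill = .data[[stat]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "white", high = "firebrick", limits = c(0, 1),
      name = if (stat == "d_prime") "D'" else expression(r^2)
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
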
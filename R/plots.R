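#' Volcano plot of per-TF differences between two groups
#'
#' @param stats_tbl The tibble returned by [diff_tf_stats()].
#' @param sig_level Significance line. Default 0.05.
#' @param label_top Label the `label_top` most significant TFs. Default 8.
#' @return A ggplot.
#' @export
plot_volcano <- function(stats_tbl, sig_level = 0.05, label_top = 8) {
  stopifnot(all(c("tf", "d_value", "p_value") %in% names(stats_tbl)))
  df <- dplyr::mutate(
    stats_tbl,
    neglog10p = -log10(pmax(.data$p_value, 1e-300)),
    direction = dplyr::case_when(
      .data$p_value < sig_level & .data$d_value > 0 ~ "up",
      .data$p_value < sig_level & .data$d_value < 0 ~ "down",
      TRUE ~ "n.s."))
  lab <- utils::head(df[order(df$p_value), ], label_top)
  ggplot2::ggplot(df, ggplot2::aes(.data$d_value, .data$neglog10p,
                                   colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(sig_level), linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$tf),
                       vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue", n.s. = "grey60")) +
    ggplot2::labs(x = "d-value (mean difference)", y = "-log10 p (U-test)",
                  colour = NULL)
}

#' PCA plot of start, end and perturbed cells
#'
#' @param coords The tibble returned by [pca_coords()].
#' @return A ggplot.
#' @export
plot_pca <- function(coords) {
  stopifnot(all(c("set", "PC1", "PC2") %in% names(coords)))
  ggplot2::ggplot(coords, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = .data$set,
                                       shape = .data$set)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(start = 16, end = 16,
                                           perturb = 4)) +
    ggplot2::labs(colour = NULL, shape = NULL)
}
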
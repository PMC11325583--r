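#' Volcano plot of a differential table
#'
#' Upregulated proteins (p below alpha, log2FC above the gate) in red,
#' downregulated in blue, everything else grey.
#'
#' @param de A `tt_de` differential table.
#' @param label_top Label the `label_top` smallest p-values (default 0,
#'   no labels).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, label_top = 0) {
  vt <- volcano_table(de)
  p <- ggplot2::ggplot(vt, ggplot2::aes(.data$log2fc, .data$neg_log10_p,
                                        colour = .data$reg_class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#2b6cb0",
                                            not_significant = "grey65")) +
    ggplot2::geom_hline(yintercept = -log10(attr(de, "alpha")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(de, "fc_cut"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2 fold change (cold - warm)",
                  y = "-log10 p", colour = NULL,
                  title = attr(de, "tissue") %||% NULL) +
    ggplot2::theme_minimal()
  if (label_top > 0) {
    lab <- vt[order(-vt$neg_log10_p), ][seq_len(min(label_top, nrow(vt))), ]
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(label = .data$protein),
                                vjust = -0.6, size = 2.8,
                                show.legend = FALSE)
  }
  p
}

#' @rdname plot_volcano
#' @param object A `tt_de` object.
#' @param ... Passed to [plot_volcano()].
#' @method autoplot tt_de
#' @export
autoplot.tt_de <- function(object, ...) plot_volcano(object, ...)

#' Crosstalk score plot
#'
#' Each ligand-receptor pair plotted by its change in summed log2 abundance
#' (`delta_sum`) and change in regularized product score (`delta_lr`);
#' selected candidates highlighted.
#'
#' @param scores A `tt_crosstalk` score table (flag rows first with
#'   [select_candidates()] `keep_all = TRUE`, otherwise all points show as
#'   unselected).
#' @return A ggplot object.
#' @export
plot_crosstalk <- function(scores) {
  df <- tibble::as_tibble(scores)
  df$pair <- paste(df$ligand, df$receptor, sep = "-")
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_sum, .data$delta_lr,
                                   colour = .data$selected)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_lrdb), alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "delta sum score (log2 units)",
                  y = "delta LR score", size = "databases",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' @rdname plot_crosstalk
#' @param object A `tt_crosstalk` object.
#' @param ... Unused.
#' @method autoplot tt_crosstalk
#' @export
autoplot.tt_crosstalk <- function(object, ...) plot_crosstalk(object)

#' Regulator activation plot
#'
#' Horizontal bars of activation z-scores with the +/- 2 decision
#' thresholds; activated regulators in red, inhibited in blue.
#'
#' @param calls A `tt_regcalls` table from [call_all_regulators()].
#' @return A ggplot object.
#' @export
plot_regulators <- function(calls) {
  df <- dplyr::filter(tibble::as_tibble(calls), !is.na(.data$z))
  ggplot2::ggplot(df, ggplot2::aes(.data$z,
                                   stats::reorder(.data$regulator, .data$z),
                                   fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(-2, 2), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(activated = "#c0392b",
                                          inhibited = "#2b6cb0",
                                          undetermined = "grey65")) +
    ggplot2::labs(x = "activation z-score", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_regulators
#' @param object A `tt_regcalls` object.
#' @param ... Unused.
#' @method autoplot tt_regcalls
#' @export
autoplot.tt_regcalls <- function(object, ...) plot_regulators(object)
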
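#' Volcano plot of a differential-expression table
#'
#' @param object A `polarmir_de` table from [run_contrast()].
#' @param p_threshold Significance line (default 1e-4 for mRNA, use 0.05
#'   for miRNA tables).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot polarmir_de
#' @export
autoplot.polarmir_de <- function(object, p_threshold = 1e-4, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$p_value < p_threshold
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fold_change,
                                   -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 fold change",
      y = "-log10 p",
      colour = paste0("p < ", format(p_threshold)),
      title = paste0(attr(object, "treated"), " vs ", attr(object, "control"),
                     " (", attr(object, "feature_kind"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' Ranked bar chart of an enrichment table
#'
#' Bars are `-log10(p)` per gene set (labelled with the originating miRNA
#' when pooled), with a dashed line at the significance threshold
#' (`-log10(0.05)` = 1.30 by default).
#'
#' @param object A `polarmir_enrichment` table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot polarmir_enrichment
#' @export
autoplot.polarmir_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(is.na(df$mirna_id), df$set_name,
                     paste0(df$set_name, " (", df$mirna_id, ")"))
  line <- attr(object, "significance_line") %||% -log10(0.05)
  ggplot2::ggplot(df, ggplot2::aes(.data$neg_log10_p,
                                   stats::reorder(.data$label,
                                                  .data$neg_log10_p))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = line, linetype = "dashed") +
    ggplot2::labs(x = "-log10 p", y = NULL,
                  title = "Gene-set over-representation") +
    ggplot2::theme_minimal()
}

#' Correlation-versus-fold scatter of an interactome
#'
#' @param object A `polarmir_interactome` table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot polarmir_interactome
#' @export
autoplot.polarmir_interactome <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$correlation_factor,
                                   .data$log2_fold_change,
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "Pearson r with miRNA", y = "log2 fold change",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
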
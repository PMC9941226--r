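#' Volcano plot of a differential-expression table
#'
#' @param records A DE tibble from [differential_expression()] or
#'   [import_de_table()].
#' @param alpha,min_abs_fc Thresholds drawn as guide lines and used to
#'   colour the retained features.
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, alpha = 0.05, min_abs_fc = 2) {
  check_columns(records, c("feature_id", "log2fc", "p_adj"), "DE table")
  kept <- filter_de(records, alpha = alpha, min_abs_fc = min_abs_fc)
  df <- records |>
    mutate(
      status = dplyr::case_when(
        .data$feature_id %in% kept$feature_id & .data$log2fc > 0 ~ "up",
        .data$feature_id %in% kept$feature_id ~ "down",
        TRUE ~ "not DE"
      ),
      neglog_p = -log10(pmax(.data$p_adj, 1e-300))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neglog_p,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.9, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(min_abs_fc), linetype = 3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 3) +
    ggplot2::scale_colour_manual(values = c(
      "up" = "#c0392b", "down" = "#2980b9", "not DE" = "grey70"
    )) +
    ggplot2::labs(x = "log2 fold change (tumor / normal)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of one miRNA-gene fold-change pairing
#'
#' Shows the per-patient log2 fold changes of a miRNA against a candidate
#' target gene, with the fitted least-squares line — the quantity the
#' negative-correlation filter acts on.
#'
#' @param mirna_fc,gene_fc Fold-change tibbles from [patient_log2fc()].
#' @param mirna_id,gene_id The pair to display.
#' @return A ggplot object.
#' @export
plot_pair_correlation <- function(mirna_fc, gene_fc, mirna_id, gene_id) {
  x <- filter(mirna_fc, .data$feature_id == mirna_id)
  y <- filter(gene_fc, .data$feature_id == gene_id)
  df <- inner_join(select(x, "patient_id", mirna = "log2fc"),
                   select(y, "patient_id", gene = "log2fc"),
                   by = "patient_id")
  if (nrow(df) < 3) abort("fewer than 3 common patients for this pair")
  r <- pearson_r(df$mirna, df$gene, mirna_id, gene_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mirna, y = .data$gene)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#c0392b", linewidth = 0.6) +
    ggplot2::labs(
      title = sprintf("%s vs %s (r = %.2f)", mirna_id, gene_id, r),
      x = sprintf("%s log2FC", mirna_id),
      y = sprintf("%s log2FC", gene_id)
    ) +
    ggplot2::theme_minimal()
}
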
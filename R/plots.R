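#' Differential-expression vs differential-splicing region plot
#'
#' Scatter of \eqn{\ln(\mathrm{fold\ change})} against
#' \eqn{-\ln(\mathrm{FDR})}, one point per gene, with the fold-change bounds
#' and the splicing-significance line partitioning the plane into the six
#' joint-analysis regions; switch genes are emphasized.
#'
#' @param jt A `joint_table`.
#' @param thr Thresholds (for the guide lines).
#' @return A ggplot object.
#' @export
plot_joint_regions <- function(jt, thr = analysis_thresholds()) {
  thr <- as_thresholds(thr)
  df <- as_tibble(jt)
  df <- df[is.finite(df$ln_fc) & is.finite(df$neglog_fdr), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ln_fc, y = .data$neglog_fdr)) +
    ggplot2::geom_vline(xintercept = log(c(thr$fc_down, thr$fc_up)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = thr$ds_neglog_fdr,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$region),
                                     shape = .data$switch), alpha = 0.8) +
    ggplot2::scale_colour_brewer(palette = "Dark2", name = "region") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "switch") +
    ggplot2::labs(x = "ln fold change (case / control)",
                  y = expression(-ln ~ FDR)) +
    ggplot2::theme_bw()
}

#' @exportS3Method ggplot2::autoplot
autoplot.joint_table <- function(object, ...) plot_joint_regions(object, ...)

#' Plot a gene's isoform proportions by condition
#'
#' Replicate-level proportions as points over condition-mean bars, one facet
#' panel per isoform — the visual counterpart of a major-minor switch.
#'
#' @param quant An `iso_quant`.
#' @param gene_id Gene to plot.
#' @return A ggplot object.
#' @export
plot_isoform_proportions <- function(quant, gene_id) {
  iso <- quant$isoforms[quant$isoforms$gene_id == gene_id, ]
  if (!nrow(iso)) abort(paste0("gene not found: ", gene_id))
  means <- iso |>
    group_by(.data$transcript_id, .data$condition) |>
    summarise(proportion = mean(.data$proportion), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$condition, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30", width = 0.6) +
    ggplot2::geom_jitter(data = iso, width = 0.08, height = 0, size = 2,
                         colour = "steelblue") +
    ggplot2::facet_wrap(~transcript_id) +
    ggplot2::labs(title = gene_id, y = "isoform proportion") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
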
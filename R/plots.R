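#' Volcano plot of the EWAS results
#'
#' Methylation difference (percent, high minus low group) against the
#' -log10 Wald p-value, with the Bonferroni threshold drawn and DMCs
#' highlighted.
#'
#' @param ewas Tibble from [ewas_scan()].
#' @param alpha Family-wise alpha for the threshold line.
#' @param diff_threshold Methylation-difference threshold (fraction).
#' @return A ggplot object.
#' @export
plot_ewas_volcano <- function(ewas, alpha = 0.05, diff_threshold = 0.05) {
  n_tested <- ewas$n_tested[1]
  df <- dplyr::filter(ewas, !is.na(.data$p))
  df$dmc <- df$p < alpha / n_tested &
    abs(df$meth_diff) / 100 > diff_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$meth_diff,
                                   y = -log10(.data$p),
                                   colour = .data$dmc)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha / n_tested),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-100, 100) * diff_threshold,
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "methylation difference (high - low, %)",
                  y = expression(-log[10](p)), colour = "DMC") +
    ggplot2::theme_minimal()
}

#' Scatter plot of instrument effects with MR fits
#'
#' Per-instrument outcome effects against exposure effects with error bars;
#' the slopes of the fitted MR estimators are overlaid (IVW through the
#' origin, Egger with its intercept).
#'
#' @param mr_results Tibble of MR results for one CpG (from [mr_analyze()]).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(mr_results) {
  inst <- attr(mr_results, "instruments") %||% {
    stop_mm("mr_results must carry an 'instruments' attribute (use mr_analyze on a single CpG, or pass an mr_result)")
  }
  ab <- dplyr::filter(mr_results,
                      .data$method %in% c("ivw_fe", "egger", "wald_ratio"),
                      !is.na(.data$b_xy))
  ab$intercept <- ifelse(ab$method == "egger", ab$egger_intercept, 0)
  ggplot2::ggplot(inst, ggplot2::aes(x = .data$b_zx, y = .data$b_zy)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$b_zy - 1.96 * .data$se_zy,
                                        ymax = .data$b_zy + 1.96 * .data$se_zy),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$b_zx - 1.96 * .data$se_zx,
                                         xmax = .data$b_zx + 1.96 * .data$se_zx),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = ab,
                         ggplot2::aes(slope = .data$b_xy,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on methylation (b_zx)",
                  y = "SNP effect on trait (b_zy)", colour = "estimator") +
    ggplot2::theme_minimal()
}

#' Autoplot method for MR results
#' @param object An `mr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_result <- function(object, ...) plot_mr_scatter(object)

#' Plot fine-mapping posterior inclusion probabilities
#'
#' @param posterior A `locus_posterior`.
#' @return A ggplot object: PIP per SNP, top causal SNP highlighted.
#' @export
plot_finemap_pip <- function(posterior) {
  df <- tidy.locus_posterior(posterior)
  df$snp <- factor(df$snp, levels = df$snp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp, y = .data$pip,
                                   fill = .data$top_causal)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "posterior inclusion probability",
                  fill = "top causal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Autoplot method for fine-mapping posteriors
#' @param object A `locus_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.locus_posterior <- function(object, ...) plot_finemap_pip(object)

#' Plot annotation enrichment results
#'
#' @param enrichment Tibble from [annotation_enrichment()].
#' @return A ggplot object: fold enrichment per track, labelled with the
#'   empirical p-value.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$track, y = .data$fold)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("p=%.3g", .data$p_emp)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "fold enrichment (observed / expected)") +
    ggplot2::theme_minimal()
}
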
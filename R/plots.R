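# ggplot2 views of the main result types.

#' @describeIn run_permutations `autoplot()` draws the distribution of the
#'   per-run significant-gene count with the original count as a dashed
#'   line — the histogram view of how a permutation strategy shifts the
#'   number of significant genes.
#' @param object,... `autoplot` method arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.gwas_perm <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = .data$n_significant_genes)) +
    ggplot2::geom_histogram(bins = 40, fill = "firebrick", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$n_sig_genes_original,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "significant genes per permutation run", y = "runs",
      title = paste0("Significant-gene counts under ",
                     object$plan$strategy, " permutations"),
      subtitle = paste0("original analysis: ",
                        object$n_sig_genes_original, " genes (dashed)")) +
    ggplot2::theme_minimal()
}

#' @describeIn subsample_cv `autoplot()` draws the CV against the
#'   subsample size, with the conventional 0.1 criterion as a dashed
#'   reference line.
#' @param object,... `autoplot` method arguments.
#' @exportS3Method ggplot2::autoplot
autoplot.convergence_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$cv)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(x = "subsampled permutations",
                  y = "coefficient of variation of the p estimate",
                  title = "Permutation-count convergence") +
    ggplot2::theme_minimal()
}

#' @describeIn run_ora `autoplot()` shows the most enriched pathways as a
#'   -log10 q-value bar chart at the given threshold.
#' @param object,... `autoplot` method arguments; `alpha` draws the
#'   significance reference line.
#' @param alpha Pathway-level threshold drawn as reference line.
#' @param top Number of pathways displayed.
#' @exportS3Method ggplot2::autoplot
autoplot.ora_result <- function(object, alpha = 0.05, top = 20, ...) {
  d <- object |>
    filter(!.data$excluded) |>
    arrange(.data$q_enriched) |>
    head(top) |>
    mutate(pathway = factor(.data$pathway, levels = rev(.data$pathway)))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$q_enriched),
                                  y = .data$pathway)) +
    ggplot2::geom_col(fill = "darkgreen", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "-log10 BH-adjusted enrichment p", y = NULL,
                  title = "Pathway over-representation") +
    ggplot2::theme_minimal()
}

#' Enriched-versus-depleted run fractions for two strategies
#'
#' Scatter of the per-pathway fraction of enriched permutation runs under
#' one strategy against another (e.g. case-control shuffles vs SNP
#' shuffles); pathways sitting at (1, 1) are enriched in essentially every
#' run of both.
#'
#' @param perm_x,perm_y Two `gwas_perm` objects over the same pathways.
#' @return A ggplot object.
#' @export
plot_enrich_deplete <- function(perm_x, perm_y) {
  common <- intersect(perm_x$summary$pathway, perm_y$summary$pathway)
  d <- tibble(
    pathway = common,
    x = perm_x$summary$frac_enriched[match(common, perm_x$summary$pathway)],
    y = perm_y$summary$frac_enriched[match(common, perm_y$summary$pathway)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6, colour = "darkgreen") +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::labs(
      x = paste0("fraction of enriched runs (", perm_x$plan$strategy, ")"),
      y = paste0("fraction of enriched runs (", perm_y$plan$strategy, ")"),
      title = "Per-pathway enrichment concordance between strategies") +
    ggplot2::theme_minimal()
}
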
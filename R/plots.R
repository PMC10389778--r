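#' Dependence plot
#'
#' Scatter of induction fold change in background 1 (`x`) against the
#' between-background fold-change difference (`y`), coloured by the
#' dependence call, with the fitted lines of any converged side and the
#' `y = 0` reference.
#'
#' @param object A `tfdep_dependence` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfdep_dependence
#' @export
autoplot.tfdep_dependence <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$call)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::scale_colour_manual(values = c(
      dependent_impaired = "#c0392b", dependent_enhanced = "#6c3483",
      independent = "grey60")) +
    ggplot2::labs(
      x = "log2 induction fold change, background 1",
      y = "log2 FC difference (background 1 - background 2)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  for (f in list(object$fit_above, object$fit_below)) {
    if (isTRUE(f$converged) && is.finite(f$slope)) {
      p <- p + ggplot2::geom_abline(slope = f$slope, intercept = f$intercept,
                                    colour = "black", linewidth = 0.4)
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of gene-set enrichment results
#'
#' @param results Enrichment tibble from [enrich()].
#' @param max_sets Show at most this many top sets (by p-value).
#' @param alpha Reference line drawn at `-log10(alpha)`.
#' @return A ggplot object of `-log10` Bonferroni-adjusted p-values.
#' @export
plot_enrichment <- function(results, max_sets = 20, alpha = 0.05) {
  res <- head(dplyr::arrange(results, .data$p_value), max_sets)
  res$set_name <- factor(res$set_name, levels = rev(res$set_name))
  ggplot2::ggplot(res, ggplot2::aes(
    x = -log10(pmax(.data$bonferroni_p, 1e-300)), y = .data$set_name)) +
    ggplot2::geom_col(fill = "#2e86c1") +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "-log10 Bonferroni-adjusted p", y = NULL) +
    ggplot2::theme_minimal()
}
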
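#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-gene table of a dependence analysis
#'
#' @param x A `tfdep_dependence` object.
#' @param ... Unused.
#' @return Tibble with one row per gene: `gene_id`, `x`, `y`, `side`,
#'   `included`, `call`.
#' @method tidy tfdep_dependence
#' @export
tidy.tfdep_dependence <- function(x, ...) {
  x$points
}

#' One-row-per-side summary of a dependence analysis
#'
#' @param x A `tfdep_dependence` object.
#' @param ... Unused.
#' @return Tibble with one row per side: slope, intercept, r-squared,
#'   Spearman rho, bias p-value, points included, iterations, convergence.
#' @method glance tfdep_dependence
#' @export
glance.tfdep_dependence <- function(x, ...) {
  dplyr::bind_rows(lapply(list(x$fit_above, x$fit_below), function(f) {
    tibble::tibble(side = f$side, slope = f$slope, intercept = f$intercept,
                   r_squared = f$r_squared, spearman_rho = f$spearman_rho,
                   bias_p = f$bias_p, n_points = f$n_points,
                   n_iterations = f$n_iterations, converged = f$converged)
  }))
}

#' @method tidy tfdep_fit
#' @export
tidy.tfdep_fit <- function(x, ...) {
  tibble::tibble(gene_id = x$included_gene_ids, side = x$side)
}

#' @method glance tfdep_fit
#' @export
glance.tfdep_fit <- function(x, ...) {
  tibble::tibble(side = x$side, slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, spearman_rho = x$spearman_rho,
                 bias_p = x$bias_p, n_points = x$n_points,
                 n_iterations = x$n_iterations, converged = x$converged)
}
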
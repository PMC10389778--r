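#' Build the fold-change dependence point cloud
#'
#' Joins per-gene induction records from two genetic backgrounds into the
#' dependence scatter: for each gene, `x` is the log2 induction fold change
#' in background 1 and `y = x - log2fc_bg2` the difference between the two
#' backgrounds' fold changes. If the regulator distinguishing the backgrounds
#' drives induction, points pile up systematically away from `y = 0`
#' (`y > 0`: impaired induction in background 2; `y < 0`: enhanced); pure
#' technical noise scatters symmetrically around `y = 0`.
#'
#' @param records_bg1,records_bg2 Induction tibbles from [induction_test()]
#'   (need `gene_id` and `log2fc`; `records_bg1` needs `status` when
#'   subsetting by it).
#' @param subset Which background-1 genes enter the analysis: `"up"`
#'   (default, the stimulation-induced set), `"down"`, or a character vector
#'   of gene ids.
#' @return Tibble with `gene_id`, `x`, `y`. Genes of the subset missing from
#'   either record set are dropped with a warning giving the count.
#' @export
build_dependence_points <- function(records_bg1, records_bg2, subset = "up") {
  if (is.character(subset) && length(subset) == 1 &&
      subset %in% c("up", "down")) {
    genes <- records_bg1$gene_id[records_bg1$status == subset]
  } else {
    genes <- as.character(subset)
  }
  if (length(genes) == 0) abort("The gene subset is empty.")
  present <- genes[genes %in% records_bg1$gene_id &
                     genes %in% records_bg2$gene_id]
  n_dropped <- length(genes) - length(present)
  if (n_dropped > 0)
    warn(sprintf("%d gene(s) missing from one background were dropped.",
                 n_dropped))
  if (length(present) == 0) abort("No subset gene is present in both backgrounds.")
  fc1 <- records_bg1$log2fc[match(present, records_bg1$gene_id)]
  fc2 <- records_bg2$log2fc[match(present, records_bg2$gene_id)]
  pts <- tibble::tibble(gene_id = present, x = fc1, y = fc1 - fc2)
  if (!all(is.finite(pts$x)) || !all(is.finite(pts$y)))
    abort("Non-finite fold changes in the dependence points.")
  pts
}

#' Partition dependence points by the sign of y
#'
#' @param points Tibble with `x`, `y` (and usually `gene_id`).
#' @return `points` with a `side` column: `"above"` (`y > 0`), `"below"`
#'   (`y < 0`) or `"on_line"` (`y == 0`). Points on the line belong to
#'   neither regression.
#' @export
split_sides <- function(points) {
  dplyr::mutate(
    tibble::as_tibble(points),
    side = dplyr::case_when(.data$y > 0 ~ "above",
                            .data$y < 0 ~ "below",
                            TRUE ~ "on_line")
  )
}

#' Ordinary least squares line with fit diagnostics
#'
#' Closed-form OLS with intercept, plus the coefficient of determination and
#' the Spearman rank correlation (average ranks on ties). A constant-`y`
#' input returns slope 0 with `r_squared` defined as 0.
#'
#' @param points Tibble with `x` and `y`; at least two points with
#'   non-identical `x`.
#' @return A list with `slope`, `intercept`, `r_squared`, `spearman_rho`,
#'   and `n_points`.
#' @examples
#' fit_line(tibble::tibble(x = 1:3, y = c(0.5, 1.5, 2.0)))
#' @export
fit_line <- function(points) {
  x <- points$x
  y <- points$y
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2)
    abort("insufficient points for fit")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  r2 <- if (syy == 0) 0 else 1 - sum((y - intercept - slope * x)^2) / syy
  rho <- if (syy == 0) 0 else suppressWarnings(cor(x, y, method = "spearman"))
  list(slope = slope, intercept = intercept,
       r_squared = min(max(r2, 0), 1),
       spearman_rho = rho, n_points = n)
}

#' Test a fitted dependence line for systematic bias away from y = 0
#'
#' Two tests of whether one side of the dependence plot shows a systematic
#' (regulator-driven) relationship rather than symmetric technical noise:
#'
#' * `"slope"` (default): two-sided t-test of H0: slope = 0 in the OLS fit —
#'   technical noise independent of `x` gives a zero slope even after
#'   conditioning on the side, while genuine dependence tilts the cloud.
#' * `"ftest"`: extra-sum-of-squares F-test of the fitted two-parameter line
#'   against the fixed line `y = 0`:
#'   `F = ((SS0 - SS1)/2) / (SS1/(n - 2))` with `SS0 = sum(y^2)` and
#'   `SS1` the residual sum of squares, compared to an F(2, n-2) tail.
#'
#' Conventions for degenerate inputs: a perfect fit with non-zero `y`
#' (`SS1 = 0`, `SS0 > 0`) gives p = 0; all-zero `y` gives p = 1.
#'
#' @param points Tibble with `x`, `y`; at least 3 points.
#' @param fit Optional result of [fit_line()] on the same points (refitted
#'   when omitted).
#' @param method `"slope"` or `"ftest"`.
#' @return p-value in \[0, 1\].
#' @export
test_bias <- function(points, fit = NULL, method = c("slope", "ftest")) {
  method <- match.arg(method)
  n <- nrow(points)
  if (n < 3) abort("Need at least 3 points to test bias.")
  y <- points$y
  x <- points$x
  ss0 <- sum(y^2)
  if (ss0 == 0) return(1)
  if (is.null(fit)) fit <- fit_line(points)
  res <- y - fit$intercept - fit$slope * x
  ss1 <- sum(res^2)
  if (method == "ftest") {
    if (ss1 == 0) return(0)
    f <- ((ss0 - ss1) / 2) / (ss1 / (n - 2))
    return(pf(f, 2, n - 2, lower.tail = FALSE))
  }
  ## slope t-test
  sxx <- sum((x - mean(x))^2)
  if (ss1 == 0) return(if (fit$slope == 0) 1 else 0)
  se <- sqrt(ss1 / (n - 2) / sxx)
  tstat <- fit$slope / se
  2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
}

#' Iterative Euclidean-distance filtering of one side of the dependence plot
#'
#' Robustly fits a regression line to the points on one side of `y = 0` by
#' repeating: (1) fit an OLS line to the currently included points (initially
#' all); (2) compute every point's perpendicular (Euclidean point-to-line)
#' distance `|y - a - b x| / sqrt(1 + b^2)` to that line; (3) include exactly
#' the points within `k` robust standard deviations (1.4826 x median absolute
#' distance of the currently included points) of the line. Iteration stops
#' when an inclusion set repeats (fixed point or cycle — on a cycle the
#' lexicographically smallest set encountered in it is reported) or after
#' `max_iterations`. The procedure is deterministic and scale-free:
#' multiplying all coordinates by a positive constant leaves the inclusion
#' set unchanged.
#'
#' @param points Tibble with `gene_id`, `x`, `y` for one side.
#' @param side Label stored in the result (`"above"` or `"below"`).
#' @param k Distance multiplier on the robust sigma (default 2.5).
#' @param max_iterations Iteration cap (default 50).
#' @param min_points Minimum points required to fit; if the side (or any
#'   iteration's inclusion set) falls below it, the fit is returned
#'   unconverged with an empty inclusion set and `bias_p = 1`.
#' @param bias_method Passed to [test_bias()].
#' @return An object of class `"tfdep_fit"`: a list with `side`, `slope`,
#'   `intercept`, `r_squared`, `spearman_rho`, `bias_p`, `n_points`,
#'   `included_gene_ids`, `n_iterations`, `converged`.
#' @export
iterative_filter <- function(points, side = "above", k = 2.5,
                             max_iterations = 50, min_points = 3,
                             bias_method = c("slope", "ftest")) {
  bias_method <- match.arg(bias_method)
  if (k <= 0) abort("`k` must be positive.")
  if (max_iterations < 1) abort("`max_iterations` must be at least 1.")
  points <- tibble::as_tibble(points)
  empty_fit <- function(n_iter) {
    structure(list(side = side, slope = NA_real_, intercept = NA_real_,
                   r_squared = NA_real_, spearman_rho = NA_real_,
                   bias_p = 1, n_points = 0L,
                   included_gene_ids = character(), n_iterations = n_iter,
                   converged = FALSE),
              class = "tfdep_fit")
  }
  if (nrow(points) < min_points) return(empty_fit(1L))

  key <- function(idx) paste(sort(points$gene_id[idx]), collapse = "\r")
  included <- seq_len(nrow(points))
  seen_keys <- character()
  seen_sets <- list()
  converged <- FALSE
  iter <- 0L
  final <- included

  while (iter < max_iterations) {
    iter <- iter + 1L
    if (length(included) < min_points ||
        length(unique(points$x[included])) < 2)
      return(empty_fit(iter))
    fit <- fit_line(points[included, ])
    d_all <- abs(points$y - fit$intercept - fit$slope * points$x) /
      sqrt(1 + fit$slope^2)
    sigma <- 1.4826 * median(d_all[included])
    new_included <- which(d_all <= k * sigma)
    kk <- key(new_included)
    hit <- match(kk, c(seen_keys, key(included)))
    seen_keys <- c(seen_keys, key(included))
    seen_sets <- c(seen_sets, list(included))
    if (!is.na(hit)) {
      ## cycle from iteration `hit` to now; report the lexicographically
      ## smallest inclusion set within the cycle
      cycle_sets <- c(seen_sets[seq(hit, length(seen_sets))], list(new_included))
      keys <- vapply(cycle_sets, key, character(1))
      final <- cycle_sets[[order(keys)[1]]]
      converged <- TRUE
      break
    }
    included <- new_included
    final <- included
  }

  if (length(final) < min_points || length(unique(points$x[final])) < 2)
    return(empty_fit(iter))
  fit <- fit_line(points[final, ])
  bias_p <- if (length(final) >= 3)
    test_bias(points[final, ], fit, method = bias_method) else 1
  structure(
    list(side = side, slope = fit$slope, intercept = fit$intercept,
         r_squared = fit$r_squared, spearman_rho = fit$spearman_rho,
         bias_p = bias_p, n_points = length(final),
         included_gene_ids = points$gene_id[final],
         n_iterations = iter, converged = converged),
    class = "tfdep_fit"
  )
}

#' @export
print.tfdep_fit <- function(x, ...) {
  cat(sprintf(
    "%s-side fit: slope %.4g, intercept %.4g, r2 %.4g, Spearman rho %.4g\n",
    x$side, x$slope, x$intercept, x$r_squared, x$spearman_rho))
  cat(sprintf("  bias p %.3g | %d points included | %d iteration(s) | %s\n",
              x$bias_p, x$n_points, x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Call genes dependent or independent from the side fits
#'
#' A gene is `dependent_impaired` when its point lies above `y = 0`, it
#' survived the iterative filter on the above side, and that side's bias test
#' is significant (`bias_p < alpha_bias`); `dependent_enhanced` symmetrically
#' below. All other genes — excluded by the filter, exactly on the line, or
#' on a side without significant bias — are `independent`.
#'
#' @param points Tibble with `gene_id`, `x`, `y` (all sides).
#' @param fit_above,fit_below `tfdep_fit` objects from [iterative_filter()];
#'   `NULL` is treated as an unconverged side.
#' @param alpha_bias Significance level for the bias test (default 0.05).
#' @return Tibble `gene_id`, `side`, `included`, `call`.
#' @export
call_dependence <- function(points, fit_above, fit_below, alpha_bias = 0.05) {
  pts <- split_sides(points)
  inc_above <- if (!is.null(fit_above) && fit_above$converged &&
                   fit_above$bias_p < alpha_bias)
    fit_above$included_gene_ids else character()
  inc_below <- if (!is.null(fit_below) && fit_below$converged &&
                   fit_below$bias_p < alpha_bias)
    fit_below$included_gene_ids else character()
  included_any <- function(f) if (is.null(f)) character() else f$included_gene_ids
  dplyr::mutate(
    pts,
    included = .data$gene_id %in% c(included_any(fit_above),
                                    included_any(fit_below)),
    call = dplyr::case_when(
      .data$gene_id %in% inc_above ~ "dependent_impaired",
      .data$gene_id %in% inc_below ~ "dependent_enhanced",
      TRUE ~ "independent"
    )
  )
}

#' Two-background dependence analysis of stimulus-induced genes
#'
#' End-to-end wrapper around the dependence method: build the point cloud
#' from two backgrounds' induction records ([build_dependence_points()]),
#' split it by the sign of `y` ([split_sides()]), run the iterative
#' Euclidean-distance filter on each side ([iterative_filter()]), and call
#' each gene dependent or independent ([call_dependence()]).
#'
#' @inheritParams build_dependence_points
#' @inheritParams iterative_filter
#' @param alpha_bias Significance level for the per-side bias test.
#' @return An object of class `"tfdep_dependence"`: a list with `points`
#'   (tibble `gene_id, x, y, side, included, call`), `fit_above`,
#'   `fit_below`, and the configuration. Use [generics::tidy()] for the
#'   per-gene table, [generics::glance()] for the per-side fit summary, and
#'   [ggplot2::autoplot()] for the dependence plot.
#' @examples
#' sim <- simulate_experiment(n_genes = 400, frac_induced = 0.25,
#'                            frac_dependent_impaired = 0.8,
#'                            n_replicates = 4, seed = 3)
#' cpm <- normalize_expression(sim$counts, "counts", "cpm")
#' de_wt <- induction_test(cpm, sim$design, "WT")
#' de_ko <- induction_test(cpm, sim$design, "KO")
#' dep <- dependence_analysis(de_wt, de_ko)
#' generics::glance(dep)
#' @export
dependence_analysis <- function(records_bg1, records_bg2, subset = "up",
                                k = 2.5, max_iterations = 50, min_points = 3,
                                alpha_bias = 0.05,
                                bias_method = c("slope", "ftest")) {
  bias_method <- match.arg(bias_method)
  pts <- build_dependence_points(records_bg1, records_bg2, subset = subset)
  sided <- split_sides(pts)
  fit_above <- iterative_filter(sided[sided$side == "above", ],
                                side = "above", k = k,
                                max_iterations = max_iterations,
                                min_points = min_points,
                                bias_method = bias_method)
  fit_below <- iterative_filter(sided[sided$side == "below", ],
                                side = "below", k = k,
                                max_iterations = max_iterations,
                                min_points = min_points,
                                bias_method = bias_method)
  calls <- call_dependence(pts, fit_above, fit_below, alpha_bias = alpha_bias)
  structure(
    list(points = calls, fit_above = fit_above, fit_below = fit_below,
         config = list(subset = subset, k = k,
                       max_iterations = max_iterations,
                       min_points = min_points, alpha_bias = alpha_bias,
                       bias_method = bias_method)),
    class = "tfdep_dependence"
  )
}

#' @export
print.tfdep_dependence <- function(x, ...) {
  cat(sprintf("Dependence analysis of %d genes (subset: %s)\n",
              nrow(x$points), x$config$subset))
  tab <- table(x$points$call)
  cat("  calls:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  print(x$fit_above)
  print(x$fit_below)
  invisible(x)
}
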
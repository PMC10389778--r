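#' Log2 fold change between two group means
#'
#' `log2((mean_stim + c) / (mean_unstim + c))` with pseudocount `c`, so two
#' zero means give a fold change of exactly 0.
#'
#' @param mean_stim,mean_unstim Non-negative group means of normalized
#'   expression.
#' @param pseudocount Positive stabilizer (default 1).
#' @return Log2 fold change (vectorized).
#' @examples
#' log2_fold_change(31, 7)   # log2(32/8) = 2
#' @export
log2_fold_change <- function(mean_stim, mean_unstim, pseudocount = 1) {
  if (any(pseudocount <= 0)) abort("`pseudocount` must be positive.")
  if (any(mean_stim < 0) || any(mean_unstim < 0))
    abort("Group means must be non-negative.")
  log2((mean_stim + pseudocount) / (mean_unstim + pseudocount))
}

#' Welch two-sample test between stimulated and unstimulated replicates
#'
#' Two-sided Welch (unequal-variance) t-test, symmetric in group order.
#' Degenerate inputs are resolved deterministically rather than erroring, so
#' noise-free simulated data can flow through the pipeline: with fewer than
#' two replicates in either group the p-value is 1 (with a warning); when
#' both groups have zero variance the p-value is 1 if the means are equal and
#' 0 otherwise.
#'
#' @param values_stim,values_unstim Numeric replicate values (typically
#'   log2(normalized + 1)).
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' two_group_test(c(1.1, 1.3, 0.9), c(3.2, 2.8, 3.1))
#' @export
two_group_test <- function(values_stim, values_unstim) {
  if (length(values_stim) < 2 || length(values_unstim) < 2) {
    warn("Fewer than 2 replicates in a group; p-value set to 1.")
    return(1)
  }
  v1 <- stats::var(values_stim)
  v2 <- stats::var(values_unstim)
  if (v1 == 0 && v2 == 0) {
    return(if (mean(values_stim) == mean(values_unstim)) 1 else 0)
  }
  t.test(values_stim, values_unstim, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise at least `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    abort("`p` must contain p-values in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Classify induction status from fold change and adjusted p-value
#'
#' Applies the threshold rule used for volcano-style calls: a gene is `up`
#' when its linear fold change is at least `up_fc` and `adj_p < alpha`,
#' `down` when the fold change is at most `down_fc` and `adj_p < alpha`, and
#' `ns` otherwise. Thresholds are given on the linear scale (the default
#' 2 / 0.5 pair corresponds to |log2 fold change| >= 1; the 1.5 / 0.66 preset
#' matches the looser dysregulation screen).
#'
#' @param records Tibble with at least `log2fc` and `adj_p` columns.
#' @param up_fc,down_fc Linear fold-change thresholds
#'   (`up_fc > 1 > down_fc > 0`).
#' @param alpha Adjusted-p significance cutoff in (0, 1).
#' @return `records` with a `status` column (`"up"`, `"down"`, `"ns"`).
#' @export
classify_induction <- function(records, up_fc = 2, down_fc = 0.5,
                               alpha = 0.05) {
  check_thresholds(up_fc, down_fc, alpha)
  if (!all(c("log2fc", "adj_p") %in% names(records)))
    abort("`records` must have `log2fc` and `adj_p` columns.")
  dplyr::mutate(
    tibble::as_tibble(records),
    status = dplyr::case_when(
      .data$log2fc >= log2(up_fc) & .data$adj_p < alpha ~ "up",
      .data$log2fc <= log2(down_fc) & .data$adj_p < alpha ~ "down",
      TRUE ~ "ns"
    )
  )
}

#' Per-gene induction statistics for one background
#'
#' For every gene, compares stimulated versus unstimulated replicates of one
#' genetic background in a normalized expression matrix: log2 fold change of
#' the group means (pseudocounted), a Welch t-test on `log2(value +
#' pseudocount)` replicate values, Benjamini-Hochberg adjustment across the
#' tested genes, and threshold classification.
#'
#' Genes below the expression filter (group mean normalized value below
#' `min_expression` in both conditions) are dropped before testing, so the
#' adjustment is computed over the genes actually analysed.
#'
#' Per-column scalings such as CPM, FPKM or TPM divide by the observed
#' library total, so when a sizeable fraction of the transcriptome is
#' induced every gene's apparent fold change is deflated by the inflated
#' stimulated totals (composition bias). With `center_fc = TRUE` (default)
#' the per-gene log2 fold changes are re-centred on their median across the
#' tested genes, under the standard assumption that the majority of genes do
#' not respond to stimulation; this plays the role of the size-factor
#' correction in count-model DE engines. Set it to `FALSE` to keep raw
#' ratio-of-means fold changes.
#'
#' @param expr Wide normalized expression tibble (`gene_id` + samples).
#' @param design Design tibble with `sample_id`, `background`, `condition`.
#' @param background Background label to analyse (e.g. `"WT"`).
#' @param condition_labels Length-2 labels, unstimulated first.
#' @param pseudocount Positive stabilizer for fold change and log values.
#' @param min_expression Expression filter: keep genes whose mean normalized
#'   value reaches this in at least one condition (default 1; `0` disables).
#' @param center_fc Median-centre the log2 fold changes across tested genes
#'   to remove library-composition bias (default `TRUE`).
#' @inheritParams classify_induction
#' @return Tibble with one row per tested gene: `gene_id`, `background`,
#'   `log2fc`, `p_value`, `adj_p`, `status`.
#' @examples
#' sim <- simulate_experiment(n_genes = 50, frac_induced = 0.3, seed = 1)
#' cpm <- normalize_expression(sim$counts, "counts", "cpm")
#' induction_test(cpm, sim$design, background = "WT")
#' @export
induction_test <- function(expr, design, background,
                           condition_labels = c("unstimulated", "stimulated"),
                           pseudocount = 1, min_expression = 1,
                           center_fc = TRUE,
                           up_fc = 2, down_fc = 0.5, alpha = 0.05) {
  expr <- check_expr(expr)
  check_thresholds(up_fc, down_fc, alpha)
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  if (!background %in% design$background)
    abort(sprintf("Background '%s' not present in the design.", background))
  ids_un <- design$sample_id[design$background == background &
                               design$condition == condition_labels[1]]
  ids_st <- design$sample_id[design$background == background &
                               design$condition == condition_labels[2]]
  if (length(ids_un) == 0 || length(ids_st) == 0)
    abort("Both conditions need at least one sample in this background.")
  m_un <- as.matrix(expr[ids_un])
  m_st <- as.matrix(expr[ids_st])

  mean_un <- rowMeans(m_un)
  mean_st <- rowMeans(m_st)
  keep <- pmax(mean_un, mean_st) >= min_expression
  if (!any(keep)) abort("No genes pass the expression filter.")

  l_un <- log2(m_un[keep, , drop = FALSE] + pseudocount)
  l_st <- log2(m_st[keep, , drop = FALSE] + pseudocount)
  pvals <- vapply(seq_len(nrow(l_un)), function(i) {
    suppressWarnings(two_group_test(l_st[i, ], l_un[i, ]))
  }, numeric(1))

  fc <- log2_fold_change(mean_st[keep], mean_un[keep], pseudocount)
  if (isTRUE(center_fc)) fc <- fc - median(fc)

  tibble::tibble(
    gene_id = expr$gene_id[keep],
    background = background,
    log2fc = fc,
    p_value = pvals,
    adj_p = bh_adjust(pvals)
  ) |>
    classify_induction(up_fc = up_fc, down_fc = down_fc, alpha = alpha)
}

check_thresholds <- function(up_fc, down_fc, alpha) {
  if (!(up_fc > 1 && down_fc < 1 && down_fc > 0))
    abort("Need `up_fc` > 1 > `down_fc` > 0.")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  invisible(TRUE)
}
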
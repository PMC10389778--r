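#' Convert an FPKM column to TPM
#'
#' Rescales fragments-per-kilobase-per-million values to
#' transcripts-per-million: `tpm_i = fpkm_i / sum(fpkm) * 1e6`. Each
#' converted column sums to one million.
#'
#' @param fpkm Numeric vector of non-negative FPKM values for one sample.
#' @return Numeric vector of TPM values summing to 1e6.
#' @examples
#' fpkm_to_tpm(c(2, 3, 5))
#' @export
fpkm_to_tpm <- function(fpkm) {
  check_nonneg(fpkm, "fpkm")
  total <- sum(fpkm)
  if (total <= 0) abort("Cannot convert an all-zero FPKM column to TPM.")
  fpkm / total * 1e6
}

#' Convert a raw count column to counts per million
#'
#' @param counts Numeric vector of non-negative counts for one sample.
#' @return Numeric vector of CPM values (`counts / library_size * 1e6`).
#' @examples
#' counts_to_cpm(c(1, 3))
#' @export
counts_to_cpm <- function(counts) {
  check_nonneg(counts, "counts")
  total <- sum(counts)
  if (total <= 0) abort("Cannot compute CPM for a zero-count library.")
  counts / total * 1e6
}

#' Convert a raw count column to FPKM
#'
#' `fpkm_i = counts_i * 1e9 / (library_size * length_i)`.
#'
#' @param counts Numeric vector of non-negative counts for one sample.
#' @param gene_lengths_bp Positive gene lengths in base pairs, one per gene.
#' @return Numeric vector of FPKM values.
#' @examples
#' counts_to_fpkm(c(100, 100), c(1000, 2000))
#' @export
counts_to_fpkm <- function(counts, gene_lengths_bp) {
  check_nonneg(counts, "counts")
  if (length(gene_lengths_bp) != length(counts) || anyNA(gene_lengths_bp))
    abort("`gene_lengths_bp` must supply one finite length per gene.")
  if (any(gene_lengths_bp <= 0)) abort("Gene lengths must be positive.")
  total <- sum(counts)
  if (total <= 0) abort("Cannot compute FPKM for a zero-count library.")
  counts * 1e9 / (total * gene_lengths_bp)
}

#' Normalize an expression matrix
#'
#' Converts a wide gene-by-sample expression table between units. Counts can
#' be converted to CPM (no lengths needed) or FPKM/TPM (lengths required);
#' FPKM can be rescaled to TPM. Every TPM column sums to one million by
#' construction.
#'
#' @param expr Wide tibble/data frame: a `gene_id` column plus one numeric
#'   column per sample.
#' @param from Unit of `expr`: `"counts"` or `"fpkm"`.
#' @param to Target unit: `"cpm"`, `"fpkm"` or `"tpm"` from counts; `"tpm"`
#'   from FPKM.
#' @param gene_lengths Tibble with `gene_id`, `length_bp`; required for
#'   FPKM/TPM from counts.
#' @return A tibble of the same shape as `expr` in the target unit, with a
#'   `"unit"` attribute recording it.
#' @examples
#' expr <- tibble::tibble(gene_id = c("a", "b"), s1 = c(2, 6), s2 = c(1, 3))
#' normalize_expression(expr, from = "counts", to = "cpm")
#' @export
normalize_expression <- function(expr,
                                 from = c("counts", "fpkm"),
                                 to = c("cpm", "fpkm", "tpm"),
                                 gene_lengths = NULL) {
  from <- match.arg(from)
  to <- match.arg(to)
  expr <- check_expr(expr)
  samples <- setdiff(names(expr), "gene_id")
  if (from == "fpkm" && to != "tpm")
    abort("From FPKM only conversion to TPM is supported.")
  fun <- if (from == "fpkm") {
    fpkm_to_tpm
  } else if (to == "cpm") {
    counts_to_cpm
  } else {
    if (is.null(gene_lengths))
      abort("`gene_lengths` is required to compute FPKM or TPM from counts.")
    lens <- gene_lengths$length_bp[match(expr$gene_id, gene_lengths$gene_id)]
    if (anyNA(lens))
      abort("`gene_lengths` is missing lengths for some genes in `expr`.")
    if (to == "fpkm") function(x) counts_to_fpkm(x, lens)
    else function(x) fpkm_to_tpm(counts_to_fpkm(x, lens))
  }
  out <- dplyr::mutate(expr, dplyr::across(dplyr::all_of(samples), fun))
  attr(out, "unit") <- to
  out
}

#' Per-gene log2 mean expression of one design group
#'
#' Averages the normalized values of the replicates belonging to one
#' (background, condition) group and returns `log2(mean + pseudocount)` per
#' gene.
#'
#' @param expr Wide expression tibble (`gene_id` + sample columns), already
#'   normalized.
#' @param design Sample design tibble with `sample_id`, `background`,
#'   `condition`.
#' @param background,condition Labels selecting the group.
#' @param pseudocount Positive stabilizer added before the log (default 1, so
#'   zero expression maps to 0).
#' @return Tibble with `gene_id` and `log2_mean`.
#' @export
log2_mean_expression <- function(expr, design, background, condition,
                                 pseudocount = 1) {
  expr <- check_expr(expr)
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  ids <- design$sample_id[design$background == background &
                            design$condition == condition]
  if (length(ids) == 0)
    abort(sprintf("No samples for group (%s, %s) in the design.",
                  background, condition))
  missing <- setdiff(ids, names(expr))
  if (length(missing) > 0)
    abort(sprintf("Design samples absent from the matrix: %s",
                  paste(missing, collapse = ", ")))
  m <- as.matrix(expr[ids])
  tibble::tibble(gene_id = expr$gene_id,
                 log2_mean = log2(rowMeans(m) + pseudocount))
}

#' Read / write wide expression tables
#'
#' Tab-separated tables with a `gene_id` first column and one numeric column
#' per sample, as written by [write_expression_tsv()]. A round trip preserves
#' values to full precision and row/column order.
#'
#' @param path File path.
#' @return `read_expression_tsv()`: a wide expression tibble.
#' @export
read_expression_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           .default = readr::col_double()
                         ))
  check_expr(out)
}

#' @rdname read_expression_tsv
#' @param expr Wide expression tibble.
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(check_expr(expr), path)
  invisible(path)
}

## -- internal validators -----------------------------------------------------

check_nonneg <- function(x, nm) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x))
    abort(sprintf("`%s` must be a non-empty numeric vector without NA.", nm))
  if (any(x < 0)) abort(sprintf("`%s` contains negative values.", nm))
  invisible(x)
}

check_expr <- function(expr) {
  if (!is.data.frame(expr) || !"gene_id" %in% names(expr))
    abort("Expression table must be a data frame with a `gene_id` column.")
  expr <- tibble::as_tibble(expr)
  if (anyDuplicated(expr$gene_id)) abort("Duplicate gene ids in the matrix.")
  samples <- setdiff(names(expr), "gene_id")
  if (length(samples) == 0) abort("Expression table has no sample columns.")
  if (anyDuplicated(samples)) abort("Duplicate sample ids in the matrix.")
  vals <- as.matrix(expr[samples])
  if (!is.numeric(vals) || anyNA(vals))
    abort("Expression values must be numeric and non-missing.")
  if (any(vals < 0)) abort("Expression values must be non-negative.")
  expr
}
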
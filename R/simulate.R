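#' Simulate a two-background, two-condition RNA-seq induction experiment
#'
#' Generates a gene-by-sample count matrix for a factorial design with two
#' genetic backgrounds (e.g. wild-type and knockout) and two conditions
#' (unstimulated, stimulated), together with the per-gene ground truth needed
#' to benchmark the downstream dependence analysis. A configurable fraction of
#' genes is induced by stimulation in background 1; a sub-fraction of those is
#' "dependent", meaning their induction is attenuated (impaired) or amplified
#' (enhanced) in background 2.
#'
#' The expected count of gene \eqn{g} in sample \eqn{s} is
#' \deqn{\mu_{gs} = L_s \, q_g \, 2^{\beta_g \, I[\mathrm{stimulated}] \, \delta_{gs}}}
#' where \eqn{L_s} is the library size (log-normal around \eqn{10^7}),
#' \eqn{q_g} a log-normal baseline relative abundance, \eqn{\beta_g} the true
#' log2 induction effect, and \eqn{\delta_{gs}} equals 1 in background 1 and
#' the gene's dependence factor in background 2 (1 for independent genes).
#' Counts are negative binomial with mean \eqn{\mu} and variance
#' \eqn{\mu + \phi\mu^2}. Setting `dispersion = 0` selects a deterministic
#' noise-free mode in which each count is the rounded mean exactly (not
#' Poisson), which makes analytic end-to-end checks possible.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per (background, condition) group; the
#'   matrix has `4 * n_replicates` sample columns.
#' @param frac_induced Fraction of genes induced by stimulation in
#'   background 1 (in \[0, 1\]). The induced genes are the first
#'   `ceiling(frac_induced * n_genes)` gene ids after a seeded shuffle.
#' @param frac_dependent_impaired,frac_dependent_enhanced Fractions *of the
#'   induced genes* whose induction is impaired / enhanced in background 2.
#'   Their sum must be at most 1.
#' @param base_expression_log_mean,base_expression_log_sd Parameters (natural
#'   log scale) of the log-normal baseline relative abundance \eqn{q_g}. The
#'   default mean `log(1e-5)` gives roughly 100 counts per gene at a
#'   \eqn{10^7} library.
#' @param induction_log2fc_mean,induction_log2fc_sd Normal distribution of the
#'   true log2 induction effects \eqn{\beta_g}; the mean should be at least
#'   the log2 up-classification threshold (1 for a 2-fold cutoff).
#' @param induction_log2fc_range Optional length-2 numeric; sampled
#'   \eqn{\beta_g} are clamped into this range (e.g. `c(1.2, 4)` guarantees
#'   every induced gene clears a 2-fold threshold).
#' @param dependence_factor_impaired Multiplier applied to \eqn{\beta_g} in
#'   background 2 for impaired genes; must be < 1 (0 abolishes induction).
#' @param dependence_factor_enhanced Multiplier applied to \eqn{\beta_g} in
#'   background 2 for enhanced genes; must be > 1.
#' @param dispersion Negative-binomial dispersion \eqn{\phi \ge 0}
#'   (variance \eqn{\mu + \phi\mu^2}); 0 selects the deterministic noise-free
#'   mode.
#' @param library_size_log_sd Log-sd of per-sample library sizes around
#'   \eqn{10^7}; 0 gives identical library sizes.
#' @param gene_length_range Length-2 integer range (bp) from which gene
#'   lengths are drawn uniformly, for FPKM/TPM paths.
#' @param background_labels,condition_labels Labels used in the sample design;
#'   background 1 / condition 1 come first.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   bit-identical output. `NULL` uses the current RNG state.
#'
#' @return A list of class `"tfdep_simulation"` with elements
#' \describe{
#'   \item{counts}{tibble, `gene_id` plus one column per sample.}
#'   \item{design}{tibble with `sample_id`, `background`, `condition`,
#'     `replicate`.}
#'   \item{truth}{tibble with `gene_id`, `induced`, `dependence_class`
#'     (`independent`/`impaired`/`enhanced`), `true_log2fc_bg1`,
#'     `true_log2fc_bg2`.}
#'   \item{gene_lengths}{tibble with `gene_id`, `length_bp`.}
#'   \item{params}{the validated parameter list, including the realised
#'     library sizes and per-gene baseline abundances (for diagnostics).}
#' }
#'
#' @examples
#' sim <- simulate_experiment(n_genes = 200, frac_induced = 0.2,
#'                            frac_dependent_impaired = 0.5, seed = 7)
#' sim$counts
#' dplyr::count(sim$truth, dependence_class)
#' @export
simulate_experiment <- function(n_genes = 2000,
                                n_replicates = 3,
                                frac_induced = 0.2,
                                frac_dependent_impaired = 0,
                                frac_dependent_enhanced = 0,
                                base_expression_log_mean = log(1e-5),
                                base_expression_log_sd = 1,
                                induction_log2fc_mean = 2,
                                induction_log2fc_sd = 0.5,
                                induction_log2fc_range = NULL,
                                dependence_factor_impaired = 0,
                                dependence_factor_enhanced = 2,
                                dispersion = 0.05,
                                library_size_log_sd = 0.1,
                                gene_length_range = c(200L, 10000L),
                                background_labels = c("WT", "KO"),
                                condition_labels = c("unstimulated", "stimulated"),
                                seed = NULL) {
  check_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
      abort(sprintf("`%s` must be a positive integer.", nm))
  }
  check_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      abort(sprintf("`%s` must be a fraction in [0, 1].", nm))
  }
  check_count(n_genes, "n_genes")
  check_count(n_replicates, "n_replicates")
  check_frac(frac_induced, "frac_induced")
  check_frac(frac_dependent_impaired, "frac_dependent_impaired")
  check_frac(frac_dependent_enhanced, "frac_dependent_enhanced")
  if (frac_dependent_impaired + frac_dependent_enhanced > 1)
    abort("`frac_dependent_impaired` + `frac_dependent_enhanced` must be at most 1.")
  if (!is.numeric(dispersion) || length(dispersion) != 1 || is.na(dispersion) ||
      dispersion < 0)
    abort("`dispersion` must be a non-negative number.")
  if (library_size_log_sd < 0)
    abort("`library_size_log_sd` must be non-negative.")
  if (dependence_factor_impaired < 0 || dependence_factor_impaired >= 1)
    abort("`dependence_factor_impaired` must be in [0, 1).")
  if (dependence_factor_enhanced <= 1)
    abort("`dependence_factor_enhanced` must be greater than 1.")
  if (length(gene_length_range) != 2 || any(gene_length_range < 1) ||
      gene_length_range[1] > gene_length_range[2])
    abort("`gene_length_range` must be an increasing pair of positive lengths.")
  stopifnot(length(background_labels) == 2, length(condition_labels) == 2)

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }

  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))

  ## design: bg1 first, unstimulated first, replicates innermost
  design <- tidyr::expand_grid(
    background = factor(background_labels, levels = background_labels),
    condition  = factor(condition_labels, levels = condition_labels),
    replicate  = seq_len(n_replicates)
  ) |>
    dplyr::mutate(
      sample_id = paste(.data$background, .data$condition, .data$replicate,
                        sep = "_"),
      .before = 1
    )
  n_samples <- nrow(design)

  ## truth assignment on a seeded shuffle: induced first, then impaired,
  ## then enhanced within the induced block
  shuffled <- sample(gene_ids)
  n_ind <- ceiling(frac_induced * n_genes)
  n_imp <- round(frac_dependent_impaired * n_ind)
  n_enh <- min(round(frac_dependent_enhanced * n_ind), n_ind - n_imp)
  induced_ids  <- shuffled[seq_len(n_ind)]
  impaired_ids <- induced_ids[seq_len(n_imp)]
  enhanced_ids <- if (n_enh > 0) induced_ids[n_imp + seq_len(n_enh)] else character()

  beta <- rnorm(n_genes, induction_log2fc_mean, induction_log2fc_sd)
  if (!is.null(induction_log2fc_range))
    beta <- pmin(pmax(beta, induction_log2fc_range[1]), induction_log2fc_range[2])
  names(beta) <- gene_ids
  beta[!gene_ids %in% induced_ids] <- 0

  delta <- rep(1, n_genes)
  names(delta) <- gene_ids
  delta[impaired_ids] <- dependence_factor_impaired
  delta[enhanced_ids] <- dependence_factor_enhanced

  truth <- tibble::tibble(
    gene_id = gene_ids,
    induced = gene_ids %in% induced_ids,
    dependence_class = dplyr::case_when(
      gene_ids %in% impaired_ids ~ "impaired",
      gene_ids %in% enhanced_ids ~ "enhanced",
      TRUE ~ "independent"
    ),
    true_log2fc_bg1 = unname(beta),
    true_log2fc_bg2 = unname(beta * delta)
  )

  q <- rlnorm(n_genes, base_expression_log_mean, base_expression_log_sd)
  lib_sizes <- rlnorm(n_samples, log(1e7), library_size_log_sd)
  length_pool <- seq(gene_length_range[1], gene_length_range[2])
  gene_lengths <- tibble::tibble(
    gene_id = gene_ids,
    length_bp = if (length(length_pool) == 1) rep(length_pool, n_genes)
                else sample(length_pool, n_genes, replace = TRUE)
  )

  stim <- design$condition == condition_labels[2]
  bg2  <- design$background == background_labels[2]
  ## genes x samples matrix of log2 effects actually applied
  eff <- outer(beta, as.numeric(stim)) *
    (outer(delta, as.numeric(bg2)) + outer(rep(1, n_genes), as.numeric(!bg2)))
  mu <- outer(q, lib_sizes) * 2^eff

  if (dispersion == 0) {
    counts <- round(mu)
  } else {
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
      nrow = n_genes
    )
  }
  counts_tbl <- tibble::as_tibble(
    setNames(as.data.frame(counts), design$sample_id)
  ) |>
    dplyr::mutate(gene_id = gene_ids, .before = 1)

  structure(
    list(
      counts = counts_tbl,
      design = design,
      truth = truth,
      gene_lengths = gene_lengths,
      params = list(
        n_genes = n_genes, n_replicates = n_replicates,
        frac_induced = frac_induced,
        frac_dependent_impaired = frac_dependent_impaired,
        frac_dependent_enhanced = frac_dependent_enhanced,
        base_expression_log_mean = base_expression_log_mean,
        base_expression_log_sd = base_expression_log_sd,
        induction_log2fc_mean = induction_log2fc_mean,
        induction_log2fc_sd = induction_log2fc_sd,
        induction_log2fc_range = induction_log2fc_range,
        dependence_factor_impaired = dependence_factor_impaired,
        dependence_factor_enhanced = dependence_factor_enhanced,
        dispersion = dispersion,
        library_size_log_sd = library_size_log_sd,
        gene_length_range = gene_length_range,
        background_labels = background_labels,
        condition_labels = condition_labels,
        seed = seed,
        library_sizes = setNames(lib_sizes, design$sample_id),
        baseline_abundance = setNames(q, gene_ids)
      )
    ),
    class = "tfdep_simulation"
  )
}

#' @export
print.tfdep_simulation <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Simulated induction experiment: %d genes x %d samples (%s/%s x %s/%s, %d replicates)\n",
    p$n_genes, nrow(x$design),
    p$background_labels[1], p$background_labels[2],
    p$condition_labels[1], p$condition_labels[2], p$n_replicates
  ))
  cat(sprintf("  induced: %d | impaired: %d | enhanced: %d | dispersion: %g\n",
              sum(x$truth$induced),
              sum(x$truth$dependence_class == "impaired"),
              sum(x$truth$dependence_class == "enhanced"),
              p$dispersion))
  invisible(x)
}

#' Write simulation outputs as TSV files
#'
#' Writes the count matrix, sample design, ground-truth table, and gene
#' lengths of a [simulate_experiment()] result into a directory as
#' tab-separated files (`counts.tsv`, `design.tsv`, `truth.tsv`,
#' `gene_lengths.tsv`).
#'
#' @param sim A `tfdep_simulation` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tfdep_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.tsv"),
    gene_lengths = file.path(dir, "gene_lengths.tsv")
  )
  readr::write_tsv(sim$counts, paths[["counts"]])
  readr::write_tsv(sim$design, paths[["design"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  readr::write_tsv(sim$gene_lengths, paths[["gene_lengths"]])
  invisible(paths)
}
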
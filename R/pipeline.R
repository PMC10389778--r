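#' Run the full two-background dependence pipeline
#'
#' Orchestrates every stage on files: read a count (or FPKM) matrix and
#' sample design, normalize, compute per-background induction statistics,
#' run the dependence regression with iterative filtering, optionally test
#' gene-set enrichment of the induced / downregulated / dependent gene
#' lists, and write all results plus a run manifest under `out_dir`. With
#' identical configuration and inputs the TSV/JSON payloads are
#' byte-identical; only the manifest carries a timestamp.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognised entries (defaults in parentheses):
#'   \describe{
#'     \item{counts, design}{Paths of the expression and design TSVs
#'       (required).}
#'     \item{gene_lengths}{Path of a `gene_id`/`length_bp` TSV; required for
#'       FPKM/TPM normalization from counts.}
#'     \item{gmt}{Optional path of a GMT gene-set collection; enables the
#'       enrichment stage.}
#'     \item{unit}{Unit of the input matrix: `"counts"` (default) or
#'       `"fpkm"`.}
#'     \item{normalize_to}{Target unit (`"cpm"` default for counts; FPKM
#'       input is always rescaled to `"tpm"`).}
#'     \item{backgrounds}{Length-2 character; background 1 first (defaults
#'       to the design's first two background labels).}
#'     \item{condition_labels}{Length-2 character, unstimulated first
#'       (defaults to the design's levels).}
#'     \item{up_fc, down_fc, alpha}{Induction thresholds (2, 0.5, 0.05).}
#'     \item{pseudocount, min_expression, center_fc}{DE options (1, 1, TRUE).}
#'     \item{subset}{Gene subset entering the dependence plot: `"up"`
#'       (default) or `"down"`.}
#'     \item{k, max_iterations, min_points, alpha_bias, bias_method}{Filter
#'       options (2.5, 50, 3, 0.05, `"slope"`).}
#'   }
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the output paths, the dependence object,
#'   and the manifest. Files written: `normalized.tsv`, `de_<bg>.tsv` per
#'   background, `dependence_calls.tsv`, `dependence_fit.json`, optional
#'   `enrichment_<query>.tsv`, and `manifest.json`.
#' @export
run_full_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  defaults <- list(
    unit = "counts", normalize_to = NULL, gene_lengths = NULL, gmt = NULL,
    backgrounds = NULL, condition_labels = NULL,
    up_fc = 2, down_fc = 0.5, alpha = 0.05,
    pseudocount = 1, min_expression = 1, center_fc = TRUE, subset = "up",
    k = 2.5, max_iterations = 50, min_points = 3, alpha_bias = 0.05,
    bias_method = "slope"
  )
  cfg <- modifyList(defaults, config)
  for (f in c("counts", "design")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      abort(sprintf("stage config: input file `%s` is missing.", f))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  warnings_log <- character()
  stages_done <- character()
  current_stage <- "config"
  run_stage <- function(name, fun) {
    current_stage <<- name
    out <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        abort(sprintf("stage %s: %s", name, conditionMessage(e)))
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    stages_done <<- c(stages_done, name)
    out
  }

  paths <- list()
  on.exit({
    manifest <- list(
      config = cfg[!vapply(cfg, is.null, logical(1))],
      package_version = as.character(utils::packageVersion("tfdep")),
      r_version = as.character(getRversion()),
      stages_completed = stages_done,
      partial = !("write" %in% stages_done),
      warnings = as.list(warnings_log),
      outputs = lapply(paths, basename),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, add = TRUE)

  inputs <- run_stage("read", function() {
    list(
      expr = read_expression_tsv(cfg$counts),
      design = readr::read_tsv(cfg$design, show_col_types = FALSE),
      lengths = if (!is.null(cfg$gene_lengths))
        readr::read_tsv(cfg$gene_lengths, show_col_types = FALSE)
    )
  })
  design <- inputs$design
  backgrounds <- cfg$backgrounds %||% unique(as.character(design$background))
  cond <- cfg$condition_labels %||% unique(as.character(design$condition))
  if (length(backgrounds) != 2 || length(cond) != 2)
    abort("stage config: need exactly two backgrounds and two conditions.")

  norm <- run_stage("normalize", function() {
    to <- cfg$normalize_to %||% if (cfg$unit == "fpkm") "tpm" else "cpm"
    normalize_expression(inputs$expr, from = cfg$unit, to = to,
                         gene_lengths = inputs$lengths)
  })

  de <- run_stage("differential_induction", function() {
    lapply(setNames(backgrounds, backgrounds), function(bg) {
      induction_test(norm, design, bg, condition_labels = cond,
                     pseudocount = cfg$pseudocount,
                     min_expression = cfg$min_expression,
                     center_fc = cfg$center_fc,
                     up_fc = cfg$up_fc, down_fc = cfg$down_fc,
                     alpha = cfg$alpha)
    })
  })

  dep <- run_stage("dependence_regression", function() {
    dependence_analysis(de[[1]], de[[2]], subset = cfg$subset,
                        k = cfg$k, max_iterations = cfg$max_iterations,
                        min_points = cfg$min_points,
                        alpha_bias = cfg$alpha_bias,
                        bias_method = cfg$bias_method)
  })

  enr <- NULL
  if (!is.null(cfg$gmt)) {
    enr <- run_stage("geneset_enrichment", function() {
      sets <- read_gmt(cfg$gmt)
      universe <- de[[1]]$gene_id
      queries <- list(
        induced = de[[1]]$gene_id[de[[1]]$status == "up"],
        downregulated = de[[1]]$gene_id[de[[1]]$status == "down"],
        dependent = dep$points$gene_id[dep$points$call != "independent"]
      )
      lapply(queries, function(q) {
        if (length(q) == 0) q <- character()
        enrich(q, sets, universe)
      })
    })
  }

  run_stage("write", function() {
    paths$normalized <<- file.path(out_dir, "normalized.tsv")
    write_expression_tsv(norm, paths$normalized)
    for (bg in backgrounds) {
      p <- file.path(out_dir, sprintf("de_%s.tsv", bg))
      paths[[sprintf("de_%s", bg)]] <<- p
      readr::write_tsv(de[[bg]], p)
    }
    paths$dependence_calls <<- file.path(out_dir, "dependence_calls.tsv")
    readr::write_tsv(tidy(dep), paths$dependence_calls)
    paths$dependence_fit <<- file.path(out_dir, "dependence_fit.json")
    fit_report <- lapply(list(dep$fit_above, dep$fit_below), function(f)
      lapply(unclass(f), function(v) if (length(v) > 1) as.list(v) else v))
    names(fit_report) <- c("above", "below")
    jsonlite::write_json(fit_report, paths$dependence_fit,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(enr)) {
      for (nm in names(enr)) {
        p <- file.path(out_dir, sprintf("enrichment_%s.tsv", nm))
        paths[[sprintf("enrichment_%s", nm)]] <<- p
        write_enrichment_tsv(enr[[nm]], p)
      }
    }
    invisible(NULL)
  })

  invisible(list(paths = paths, dependence = dep, de = de, enrichment = enr))
}
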
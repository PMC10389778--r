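#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` members of a `K`-gene set when `n`
#' genes are sampled without replacement from a universe of `N`:
#' `P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`. Evaluated
#' through the log-space hypergeometric CDF for numerical stability.
#'
#' @param k Observed overlap (non-negative integer).
#' @param N Universe size.
#' @param K Gene-set size within the universe (`0 <= K <= N`).
#' @param n Query size within the universe (`0 <= n <= N`).
#' @return The upper-tail probability; 1 when `k = 0`, 0 when
#'   `k > min(K, n)`.
#' @examples
#' hypergeom_upper_tail(k = 3, N = 10, K = 4, n = 5)  # 66/252
#' @export
hypergeom_upper_tail <- function(k, N, K, n) {
  ok <- function(v) is.numeric(v) && length(v) == 1 && !is.na(v) &&
    v >= 0 && v == floor(v)
  if (!ok(k) || !ok(N) || !ok(K) || !ok(n) || K > N || n > N)
    abort("Need integers with 0 <= K <= N, 0 <= n <= N, k >= 0.")
  if (k == 0) return(1)
  if (k > min(K, n)) return(0)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric gene-set enrichment with Bonferroni adjustment
#'
#' Tests a query gene list (e.g. stimulus-induced or regulator-dependent
#' genes) for over-representation in each gene set of a collection, against
#' a stated gene universe. Query genes and set members outside the universe
#' are dropped (with a warning count for the query). The Bonferroni factor is
#' the number of sets actually tested.
#'
#' @param query Character vector of query gene ids.
#' @param gene_sets Gene-set collection from [read_gmt()] (tibble with
#'   `name`, `description`, and list-column `members`).
#' @param universe Character vector of universe gene ids (e.g. all expressed
#'   genes).
#' @return Tibble with one row per set: `set_name`, `N`, `K`, `n`, `k`,
#'   `p_value`, `bonferroni_p`, sorted by `p_value` then set name. Empty
#'   query after intersection gives an empty tibble.
#' @examples
#' sets <- tibble::tibble(name = "S1", description = "",
#'                        members = list(c("a", "b", "c")))
#' enrich(c("a", "b", "d"), sets, universe = letters[1:10])
#' @export
enrich <- function(query, gene_sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  query <- unique(as.character(query))
  dropped <- sum(!query %in% universe)
  if (dropped > 0)
    warn(sprintf("%d query gene(s) outside the universe were dropped.",
                 dropped))
  query <- intersect(query, universe)
  cols <- c("set_name", "N", "K", "n", "k", "p_value", "bonferroni_p")
  if (length(query) == 0)
    return(tibble::as_tibble(setNames(
      list(character(), integer(), integer(), integer(), integer(),
           numeric(), numeric()), cols)))
  if (anyDuplicated(gene_sets$name)) abort("Gene-set names must be unique.")
  m <- nrow(gene_sets)
  res <- purrr::pmap_dfr(gene_sets, function(name, description, members, ...) {
    members <- intersect(unique(members), universe)
    k <- length(intersect(query, members))
    p <- hypergeom_upper_tail(k, length(universe), length(members),
                              length(query))
    tibble::tibble(set_name = name, N = length(universe),
                   K = length(members), n = length(query), k = k,
                   p_value = p, bonferroni_p = min(1, m * p))
  })
  dplyr::arrange(res, .data$p_value, .data$set_name)
}

#' Read a GMT gene-set file
#'
#' Parses the tab-delimited GMT format (one set per line: name, description,
#' then member genes). Duplicate members within a set are collapsed with a
#' warning; a line with fewer than three fields is an error naming the line.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble with `name`, `description`, and list-column `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("GMT file is empty.")
  parsed <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      abort(sprintf("Malformed GMT line %d: fewer than 3 tab-separated fields.",
                    i))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn(sprintf("Duplicate members in set '%s' collapsed.", fields[1]))
      members <- unique(members)
    }
    if (length(members) == 0)
      abort(sprintf("Gene set '%s' (line %d) has no members.", fields[1], i))
    tibble::tibble(name = fields[1], description = fields[2],
                   members = list(members))
  })
  out <- dplyr::bind_rows(parsed)
  if (anyDuplicated(out$name)) abort("Duplicate set names in the GMT file.")
  out
}

#' @rdname read_gmt
#' @param gene_sets Gene-set tibble as returned by `read_gmt()`.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- purrr::pmap_chr(gene_sets, function(name, description, members, ...) {
    paste(c(name, description, members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname enrich
#' @param results Enrichment tibble from `enrich()`.
#' @param path Output TSV path.
#' @export
write_enrichment_tsv <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}
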
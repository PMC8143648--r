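#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated — set name, description,
#' then the member gene ids.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (set name -> members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort("malformed GMT line (need name, description, >=1 member)")
    }
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Restrict a gene-set collection to a universe
#'
#' Intersects every set with the background universe; sets left empty are
#' dropped with a warning.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of background gene ids.
#' @return Named list of restricted, nonempty sets.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) abort("`universe` must be nonempty")
  restricted <- lapply(sets, intersect, y = universe)
  empty <- lengths(restricted) == 0
  if (any(empty)) {
    warn(paste0("dropping ", sum(empty),
                " gene set(s) empty after restriction to the universe: ",
                paste(head(names(restricted)[empty], 5), collapse = ", ")))
  }
  restricted[!empty]
}

#' Hypergeometric fold-enrichment test for one gene set
#'
#' Over-representation of a gene set among the query genes relative to a
#' background universe, reported as the fold enrichment
#' `FE = (k/n) / (K/N)` (k = query genes in the set, n = query size,
#' K = set size within the universe, N = universe size) with the
#' hypergeometric upper-tail p-value `P(X >= k)`. With `ease = TRUE` the
#' p-value uses the conservative EASE variant (one success removed).
#'
#' @param query Character vector of query gene ids (e.g. one class of
#'   differential hits).
#' @param geneset Character vector of set members.
#' @param universe Character vector of background ids; query and set are
#'   restricted to it.
#' @param ease Use the EASE-adjusted p-value.
#' @return One-row tibble: `FE`, `p`, `k`, `n`, `K`, `N`.
#' @examples
#' fold_enrichment_test(paste0("g", 1:10), paste0("g", 6:25),
#'                      paste0("g", 1:100))
#' @export
fold_enrichment_test <- function(query, geneset, universe, ease = FALSE) {
  universe <- unique(as.character(universe))
  if (!length(universe)) abort("`universe` must be nonempty")
  query <- intersect(unique(as.character(query)), universe)
  geneset <- intersect(unique(as.character(geneset)), universe)
  if (!length(query)) abort("`query` is empty (after universe restriction)")
  if (!length(geneset)) abort("`geneset` is empty (after universe restriction)")
  n <- length(query); K <- length(geneset); N <- length(universe)
  k <- length(intersect(query, geneset))
  fe <- (k / n) / (K / N)
  k_eff <- if (ease) max(k - 1L, 0L) else k
  p <- if (k_eff == 0) 1 else phyper(k_eff - 1, K, N - K, n,
                                     lower.tail = FALSE)
  tibble(FE = fe, p = p, k = k, n = n, K = K, N = N)
}

#' Fold-enrichment tests over a whole gene-set collection
#'
#' @inheritParams fold_enrichment_test
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param adjust_p Add Benjamini-Hochberg adjusted p-values across sets.
#' @return Tibble with one row per set, ordered by increasing p.
#' @export
enrich_gene_sets <- function(query, sets, universe, ease = FALSE,
                             adjust_p = FALSE) {
  sets <- gene_set_collection(sets, universe)
  if (!length(sets)) abort("no nonempty gene sets after restriction")
  res <- purrr::map(sets, fold_enrichment_test, query = query,
                    universe = universe, ease = ease)
  out <- dplyr::bind_rows(res, .id = "set")
  if (adjust_p) out$p_adj <- stats::p.adjust(out$p, "BH")
  dplyr::arrange(out, .data$p, dplyr::desc(.data$FE))
}
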
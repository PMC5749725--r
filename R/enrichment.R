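# Gene-set over-representation analysis.
#
# For a query of n genes drawn from a universe of N, the overlap k with a
# K-gene set is tested with the exact hypergeometric upper tail, and the
# family of tests across the collection is corrected with the
# Benjamini-Hochberg step-up procedure. The family size m is the size of
# the collection tested, not the number of sets reaching any overlap:
# zero-overlap sets are dropped from the output but still count in m.

#' Exact upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes without
#' replacement from a universe of `N` of which `K` are in the set. Terms are
#' evaluated in log space via `lchoose` and summed over the support, so
#' extreme tails are stable. Symmetric in `K` and `n`.
#'
#' @param k observed overlap (vectorised).
#' @param K gene-set size.
#' @param n query size.
#' @param N universe size; requires `K <= N`, `n <= N`, `k <= min(K, n)`.
#' @return `P(X >= k)`.
#' @export
#' @examples
#' hypergeom_tail(4, 28, 147, 45956)   # ~1.94e-6
hypergeom_tail <- function(k, K, n, N) {
  if (K > N || n > N) abort("set and query sizes cannot exceed the universe")
  if (any(k > pmin(K, n))) abort("overlap cannot exceed min(K, n)")
  if (any(k < 0)) abort("overlap must be non-negative")
  vapply(k, function(ki) {
    if (ki == 0L) return(1)
    hi <- min(K, n)
    j <- ki:hi
    terms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    sum(exp(terms))
  }, numeric(1))
}

#' Benjamini-Hochberg q-values with an explicit family size
#'
#' Step-up FDR adjustment `q_i = min_{j: rank_j >= rank_i} p_j * m / rank_j`
#' capped at 1, where `m` is the total number of tests in the family — which
#' may exceed the number of p-values supplied when only the sets with
#' non-zero overlap are listed. Ties share ranks by sorted order; output
#' order matches input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m family size; at least `length(p_values)`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    abort("family size m cannot be smaller than the number of p-values")
  }
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_along(p_values)
  q_sorted <- pmin(rev(cummin(rev(ranked))), 1)
  q <- numeric(length(p_values))
  q[ord] <- q_sorted
  q
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric upper-tail test of a gene query against every stored set
#' of a collection, BH-corrected over the full collection size. Sets with
#' zero overlap are omitted from the output but remain in the
#' multiple-testing family.
#'
#' @param query character vector of gene symbols (case-insensitive; a gene
#'   mutated several times still counts once).
#' @param collection a [gene_set_collection()].
#' @param N universe size (total genes the query could have hit). The
#'   default, 45956, reflects a full-genome annotation universe.
#' @return ranked result tibble: `set_name`, `set_size`, `overlap`,
#'   `overlap_genes` (comma-joined), `p_value`, `q_value`, `rank`; sorted by
#'   ascending p.
#' @export
enrich <- function(query, collection, N = 45956L) {
  query <- unique(toupper(query))
  if (!length(query)) abort("query must be non-empty")
  if (N < length(query)) abort("universe smaller than the query")
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    ov <- intersect(query, set)
    tibble(set_name = nm, set_size = length(set), overlap = length(ov),
           overlap_genes = paste(sort(ov), collapse = ","))
  })
  res <- bind_rows(rows) %>% filter(.data$overlap > 0L)
  if (!nrow(res)) {
    return(new_result_tbl(
      tibble(set_name = character(), set_size = integer(),
             overlap = integer(), overlap_genes = character(),
             p_value = numeric(), q_value = numeric(), rank = integer()),
      "enrichment"))
  }
  res$p_value <- vapply(seq_len(nrow(res)), function(i)
    hypergeom_tail(res$overlap[i], res$set_size[i], n, N), numeric(1))
  res$q_value <- bh_fdr(res$p_value, m = collection$collection_size)
  res <- res %>% arrange(.data$p_value, .data$set_name) %>%
    mutate(rank = row_number())
  new_result_tbl(res, "enrichment")
}
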
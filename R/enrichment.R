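#' Hypergeometric over-representation analysis of gene sets
#'
#' Tests each gene set for over-representation in a query list relative to
#' a universe of measured genes. The p-value for a set with `K` members in
#' the universe, a query of size `n` drawn from a universe of size `N`, and
#' `k` observed overlaps is the upper hypergeometric tail
#' P(X >= k); with `k = 0` this is 1. Benjamini-Hochberg q-values are
#' computed across all tested sets of the collection. Sets with no member
#' in the universe are skipped with a message. Rows are ordered by p-value,
#' ties broken by descending overlap then set name, so output order is
#' deterministic.
#'
#' @param query character vector of query gene symbols; must be a subset of
#'   `universe`.
#' @param universe character vector of all measured gene symbols.
#' @param sets a named list of character vectors (e.g. from [read_gmt()]),
#'   one element per gene set.
#' @return a data.frame with one row per tested set: `set_name`,
#'   `overlap_k`, `set_size_K`, `query_size_n`, `universe_N`, `p_value`,
#'   `q_value`, `overlap_genes` (comma-separated).
#' @export
ora <- function(query, universe, sets) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0)
    stop("query gene list is empty")
  out_q <- setdiff(query, universe)
  if (length(out_q) > 0)
    stop("query genes missing from universe: ",
         paste(utils::head(out_q, 5), collapse = ", "))
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must be a uniquely named list of gene vectors")

  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    K <- length(members)
    if (K == 0) return(NULL)
    hits <- intersect(members, query)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_k = k, set_size_K = K,
               query_size_n = n, universe_N = N, p_value = p,
               overlap_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    message(skipped, " gene set(s) had no member in the universe; skipped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(set_name = character(0), overlap_k = integer(0),
                      set_size_K = integer(0), query_size_n = integer(0),
                      universe_N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, -res$overlap_k, res$set_name), ]
  rownames(res) <- NULL
  res[, c("set_name", "overlap_k", "set_size_K", "query_size_n",
          "universe_N", "p_value", "q_value", "overlap_genes")]
}
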
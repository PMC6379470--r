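# Enrichment statistics: a 2x2 chi-square comparison of target
# distribution across two disease-gene lists, and generic upper-tail
# hypergeometric term enrichment over user-supplied gene sets.

#' Pearson chi-square test on a 2x2 contingency table
#'
#' For comparing how a drug's targets distribute over two disease-gene
#' lists (rows = list, columns = targeted / not targeted). No continuity
#' correction by default.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @param yates Apply the Yates continuity correction.
#' @return List with `chi2` (statistic, 1 df) and `p`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_input("need a 2x2 table")
  if (any(table < 0)) stop_input("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_input("zero marginal in contingency table")
  if (all(table == 0)) stop_input("empty contingency table")
  res <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' Hypergeometric term-enrichment test
#'
#' For each term set, tests over-representation of the query genes with
#' the upper-tail hypergeometric probability `P(X >= k)` and the fold
#' enrichment `(k/n) / (K/N)` (k = overlap, n = query size, K = term
#' size, N = universe size, all after intersection with the universe).
#' Results are filtered to `p < p_max` and fold enrichment strictly
#' greater than `min_fold`, sorted by p ascending.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param terms Named list of character vectors (term -> gene set), e.g.
#'   from [read_gmt()].
#' @param universe Character vector: the gene universe.
#' @param p_max Raw p-value cutoff (exclusive). No multiple-testing
#'   correction is applied by default; see `adjust`.
#' @param min_fold Fold-enrichment cutoff (exclusive).
#' @param adjust If `"BH"`, filter on Benjamini-Hochberg adjusted
#'   p-values instead of raw ones (reported in column `p_adjusted`).
#' @return A `data.frame` with columns `term`, `k`, `n`, `K`, `N`,
#'   `p_value`, `fold_enrichment` (and `p_adjusted` when requested).
#' @export
hypergeom_enrich <- function(query, terms, universe, p_max = 0.05,
                             min_fold = 1.0, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  universe <- unique(norm_symbols(universe))
  if (!length(universe)) stop_input("empty universe")
  query <- unique(norm_symbols(query))
  if (length(setdiff(query, universe)))
    stop_input("query genes outside the universe: ",
               paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(tm) {
    term_set <- intersect(unique(norm_symbols(terms[[tm]])), universe)
    K <- length(term_set)
    k <- length(intersect(query, term_set))
    p <- if (K == 0L || n == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K == 0L || n == 0L) 0 else (k / n) / (K / N)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p_value = p,
               fold_enrichment = fold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      fold_enrichment = numeric(), stringsAsFactors = FALSE)
  p_filter <- out$p_value
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    p_filter <- out$p_adjusted
  }
  out <- out[p_filter < p_max & out$fold_enrichment > min_fold, , drop = FALSE]
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
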
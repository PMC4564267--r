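# Over-representation analysis of a gene list against user-supplied gene
# sets by the hypergeometric upper tail, BH-corrected across sets.

#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more annotated genes in a draw of `n`
#' from a universe of `N` containing `K` annotated genes:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param N universe size.
#' @param K annotated genes in the universe.
#' @param n selected genes.
#' @param k overlap between selection and annotation.
#' @return the tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > min(K, n) || K > N || n > N)
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation of a gene list in gene sets
#'
#' Each set is first restricted to universe members (conditional
#' hypergeometric); sets with no universe member are not tested. The
#' recommended universe is the post-filter gene panel the selection was
#' made from, not the whole genome.
#'
#' @param selected_genes the gene list to test (must lie in the universe).
#' @param gene_sets list from [load_gene_sets()].
#' @param universe background gene symbols.
#' @return data.frame of class `EnrichmentTable`, one row per tested set,
#'   sorted by p-value: `set_name`, `N`, `K`, `n`, `k`, `p_value`,
#'   `p_adjusted`, `overlap_genes` (comma-joined).
#' @export
enrich <- function(selected_genes, gene_sets, universe) {
  universe <- unique(toupper(universe))
  selected <- unique(toupper(selected_genes))
  outside <- setdiff(selected, universe)
  if (length(outside))
    stop("selected gene(s) not in the universe: ",
         paste(head(outside, 5L), collapse = ", "))
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(gene_sets, function(s) {
    members <- intersect(s$genes, universe)
    if (!length(members)) return(NULL)
    hit <- sort(intersect(members, selected), method = "radix")
    data.frame(set_name = s$name, N = N, K = length(members), n = n,
               k = length(hit),
               p_value = hypergeom_tail(N, length(members), n, length(hit)),
               overlap_genes = paste(hit, collapse = ","),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    stop("no gene set overlaps the universe")
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "N", "K", "n", "k", "p_value", "p_adjusted",
               "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}
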
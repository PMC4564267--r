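# Disease-similarity profiling: per-study signed log-p expression
# variation scores, rank correlation between studies, and average-linkage
# clustering on 1 - r.

#' Expression variation profile of a study
#'
#' Per gene, `score = sign(t) * ln(p)` (p clamped to `[p_floor, 1]`): zero
#' for null genes, large negative for significant up-regulation and large
#' positive for significant down-regulation, so the profile carries both
#' the strength and the direction of differential expression. The base of
#' the log is irrelevant for the rank correlations computed downstream;
#' `negate = TRUE` emits the `-sign(t) * ln(p)` convention instead.
#'
#' @param de a `DEResult` from [run_de()].
#' @param study_id study identifier (defaults to the result's attribute).
#' @param p_floor lower clamp for p-values before taking logs.
#' @param negate flip the sign convention.
#' @return list of class `VariationProfile` with `study_id`, `genes`,
#'   `scores` (named numeric vector in the result's gene order).
#' @export
variation_profile <- function(de, study_id = attr(de, "study_id"),
                              p_floor = 1e-20, negate = FALSE) {
  scores <- sign(de$t) * log(clamp_p(de$p_value, p_floor))
  if (negate) scores <- -scores
  structure(list(study_id = study_id, genes = de$gene,
                 scores = stats::setNames(scores, de$gene)),
            class = "VariationProfile")
}

#' Pairwise correlation of variation profiles
#'
#' Kendall's tau-b (tie-corrected) or Spearman's rho between every pair of
#' study profiles, which must share one gene order.
#'
#' @param profiles list of [variation_profile()]s.
#' @param method `"kendall"` or `"spearman"`.
#' @return symmetric correlation matrix (class `CorrelationMatrix`) with a
#'   `method` attribute; rows/columns named by study.
#' @export
correlation_matrix <- function(profiles, method = c("kendall", "spearman")) {
  method <- match.arg(method)
  genes <- profiles[[1L]]$genes
  if (length(genes) < 3L) stop("need at least 3 genes to correlate profiles")
  for (p in profiles)
    if (!identical(p$genes, genes))
      stop("profiles must share an identical gene order")
  m <- vapply(profiles, function(p) unname(p$scores), numeric(length(genes)))
  colnames(m) <- vapply(profiles, `[[`, "", "study_id")
  r <- stats::cor(m, method = method)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(r, method = method, class = c("CorrelationMatrix", class(r)))
}

#' Cluster studies on their profile correlations
#'
#' Agglomerative clustering with average linkage on the dissimilarity
#' `d = 1 - r`. Studies are put in lexicographic order before clustering,
#' which makes the merge order deterministic and independent of the input
#' ordering.
#'
#' @param corr a [correlation_matrix()].
#' @return An `hclust` tree over the studies, with `distance` and
#'   `linkage` metadata attributes.
#' @export
cluster_studies <- function(corr) {
  ids <- sort(colnames(corr), method = "radix")
  d <- stats::as.dist(1 - unclass(corr)[ids, ids])
  hc <- stats::hclust(d, method = "average")
  attr(hc, "distance") <- "1 - correlation"
  attr(hc, "linkage") <- "average"
  hc
}

#' Export a study dendrogram as Newick
#'
#' @param hc an `hclust` tree from [cluster_studies()].
#' @return single Newick string with branch lengths.
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

# TRUE iff studies a and b are merged as two singletons, i.e. form their
# own 2-leaf clade; used to check that same-disease datasets pair up first.
are_siblings <- function(hc, a, b) {
  ia <- -match(a, hc$labels)
  ib <- -match(b, hc$labels)
  any(apply(hc$merge, 1L, function(row)
    all(sort(row) == sort(c(ia, ib)))))
}
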
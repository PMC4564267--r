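# Detection of genes differentially expressed across several diseases:
# per-study significance calls (top-k rank or adjusted-p), aggregation of
# studies to diseases, selection of genes hitting at least `min_diseases`
# diseases, and the union of the two criteria with provenance.

de_study_id <- function(de, fallback) {
  id <- attr(de, "study_id")
  if (is.null(id) || is.na(id)) fallback else id
}

#' Per-study significance calls
#'
#' Under the `top_k` criterion a gene is significant in a study iff its
#' p-value rank is `<= k` (boundary inclusive); under the `fdr` criterion
#' iff its BH-adjusted p-value is strictly `< alpha`.
#'
#' @param de_list list of `DEResult`s, one per study (named, or carrying a
#'   `study_id` attribute).
#' @param criterion `"top_k"` or `"fdr"`.
#' @param k rank cutoff for `top_k`.
#' @param alpha adjusted-p cutoff for `fdr`, in `(0, 1)`.
#' @return data.frame with `gene`, `study_id`, `criterion`, `significant`.
#' @export
make_calls <- function(de_list, criterion = c("top_k", "fdr"),
                       k = 100L, alpha = 0.01) {
  criterion <- match.arg(criterion)
  if (criterion == "top_k" && k <= 0) stop("'k' must be a positive count")
  if (criterion == "fdr" && (alpha <= 0 || alpha >= 1))
    stop("'alpha' must lie strictly between 0 and 1")
  ids <- names(de_list)
  if (is.null(ids)) ids <- rep(NA_character_, length(de_list))
  rows <- lapply(seq_along(de_list), function(i) {
    de <- de_list[[i]]
    sig <- if (criterion == "top_k") de$rank <= k else de$p_adjusted < alpha
    data.frame(gene = de$gene, study_id = de_study_id(de, ids[[i]]),
               criterion = criterion, significant = sig,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

as_study_disease_map <- function(manifest) {
  if (inherits(manifest, "StudyManifest")) {
    tab <- manifest_table(manifest)
  } else if (is.data.frame(manifest)) {
    tab <- manifest
  } else stop("'manifest' must be a StudyManifest or a data.frame")
  if (!all(c("study_id", "disease") %in% names(tab)))
    stop("manifest table needs 'study_id' and 'disease' columns")
  stats::setNames(tab$disease, tab$study_id)
}

#' Aggregate study-level calls to diseases
#'
#' A gene hits a disease iff it is significant in at least one of that
#' disease's studies, so a disease with several datasets is still counted
#' once.
#'
#' @param calls data.frame from [make_calls()] (one or both criteria).
#' @param manifest a [study_manifest()] or a data.frame with `study_id`
#'   and `disease` columns.
#' @return data.frame with `gene`, `criterion`, `n_diseases`, `diseases`
#'   (comma-joined, sorted).
#' @export
aggregate_to_disease <- function(calls, manifest) {
  map <- as_study_disease_map(manifest)
  unknown <- setdiff(unique(calls$study_id), names(map))
  if (length(unknown))
    stop("call(s) refer to study id(s) not in the manifest: ",
         paste(unknown, collapse = ", "))
  sig <- calls[calls$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(gene = character(), criterion = character(),
                      n_diseases = integer(), diseases = character(),
                      stringsAsFactors = FALSE))
  sig$disease <- unname(map[sig$study_id])
  pieces <- split(sig, list(sig$criterion, sig$gene), drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(d) {
    ds <- sort(unique(d$disease), method = "radix")
    data.frame(gene = d$gene[[1L]], criterion = d$criterion[[1L]],
               n_diseases = length(ds), diseases = paste(ds, collapse = ","),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$criterion, out$gene), , drop = FALSE]
}

#' Select genes shared by several diseases
#'
#' @param hits data.frame from [aggregate_to_disease()].
#' @param min_diseases minimum number of distinct diseases a gene must hit.
#' @return the qualifying rows, sorted by decreasing `n_diseases` then
#'   gene symbol.
#' @export
select_common <- function(hits, min_diseases = 3L) {
  sel <- hits[hits$n_diseases >= min_diseases, , drop = FALSE]
  sel <- sel[order(-sel$n_diseases, sel$gene), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Union of the two selection criteria with provenance
#'
#' @param set_top_k,set_fdr the [select_common()] outputs (or plain gene
#'   vectors) for the top-k and FDR criteria.
#' @return data.frame with `gene`, `in_top_k`, `in_fdr` and a `criteria`
#'   label (`"top_k"`, `"fdr"` or `"both"`), genes in lexicographic order.
#' @export
union_criteria <- function(set_top_k, set_fdr) {
  pull <- function(x) if (is.data.frame(x)) x$gene else as.character(x)
  g1 <- unique(pull(set_top_k)); g2 <- unique(pull(set_fdr))
  genes <- sort(unique(c(g1, g2)), method = "radix")
  in1 <- genes %in% g1; in2 <- genes %in% g2
  data.frame(gene = genes, in_top_k = in1, in_fdr = in2,
             criteria = ifelse(in1 & in2, "both",
                               ifelse(in1, "top_k", "fdr")),
             row.names = NULL, stringsAsFactors = FALSE)
}
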
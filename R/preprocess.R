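# Multi-study preprocessing: probe-to-gene collapse, gene-panel
# intersection, and two-stage rank-sum filtering of un-expressed and
# un-informative genes.

row_iqr <- function(m) {
  apply(m, 1L, function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7L)
    q[2L] - q[1L]
  })
}

row_sd <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums(m * m) - n * mu * mu, 0) / (n - 1L))
}

# C-locale lexicographic sort, independent of the session locale
sort_c <- function(x) sort(x, method = "radix")

#' Collapse probes to genes by largest IQR
#'
#' When several probes map to one gene symbol, the probe whose expression
#' values have the largest interquartile range across all samples (type-7
#' linearly interpolated quartiles) represents the gene; the retained row
#' is that probe's row, unchanged. Ties keep the probe appearing first in
#' file order. Probes with an empty or missing annotation are dropped.
#'
#' @param dataset probe-level [expression_dataset()].
#' @param probe_map data.frame from [load_probe_map()].
#' @return A gene-level [expression_dataset()], genes ordered by first
#'   appearance of their probes.
#' @export
collapse_probes_iqr <- function(dataset, probe_map) {
  sym <- probe_map$gene_symbol[match(rownames(dataset$values), probe_map$probe_id)]
  sym[is.na(sym)] <- ""
  keep <- nzchar(sym)
  if (!any(keep))
    stop("study '", dataset$study_id, "': no probe maps to an annotated gene")
  v <- dataset$values[keep, , drop = FALSE]
  sym <- sym[keep]
  iqr <- row_iqr(v)
  idx <- split(seq_len(nrow(v)), factor(sym, levels = unique(sym)))
  pick <- vapply(idx, function(i) i[which.max(iqr[i])], integer(1L))
  out <- v[pick, , drop = FALSE]
  rownames(out) <- names(idx)
  expression_dataset(out, dataset$group, dataset$study_id, dataset$disease)
}

#' Restrict datasets to their common genes
#'
#' Every dataset is restricted to the set intersection of gene symbols, in
#' one canonical (C-locale lexicographic) order shared by all.
#'
#' @param datasets list of gene-level [expression_dataset()]s.
#' @return list of datasets on the shared, ordered gene panel.
#' @export
intersect_genes <- function(datasets) {
  panels <- lapply(datasets, function(d) rownames(d$values))
  common <- Reduce(intersect, panels)
  if (!length(common))
    stop("no genes are shared by all datasets")
  common <- sort_c(common)
  lapply(datasets, function(d)
    expression_dataset(d$values[common, , drop = FALSE], d$group,
                       d$study_id, d$disease))
}

filter_report <- function(n_input, n_common, n_unexpr, n_uninf) {
  r <- list(n_input_genes = n_input,
            n_after_intersection = n_common,
            n_removed_unexpressed = n_unexpr,
            n_removed_uninformative = n_uninf,
            n_retained = n_common - n_unexpr - n_uninf)
  stopifnot(all(unlist(r) >= 0L))
  structure(r, class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf(paste0("FilterReport: %d input genes, %d after intersection, ",
                     "%d removed as un-expressed, %d as un-informative, %d retained\n"),
              x$n_input_genes, x$n_after_intersection,
              x$n_removed_unexpressed, x$n_removed_uninformative, x$n_retained))
  invisible(x)
}

#' Remove un-expressed and un-informative genes by cross-study rank sums
#'
#' Stage 1 ranks each gene's mean intensity within each dataset (rank 1 =
#' smallest, average ranks for ties), sums the ranks across datasets and
#' removes the `floor(frac_mean * G)` genes with the smallest rank sums as
#' un-expressed. Stage 2 repeats the procedure with standard deviations on
#' the survivors, removing `floor(frac_sd * G')` genes as un-informative.
#' Rank-sum ties are broken by lexicographic gene symbol so removal is
#' deterministic. Means and SDs use all samples (cases and controls),
#' since filtering precedes any group comparison.
#'
#' @param datasets list of [expression_dataset()]s sharing one gene list.
#' @param frac_mean,frac_sd fractions in `[0, 1)` to remove at each stage.
#' @param n_input_genes optional pre-intersection gene count for the report.
#' @return `list(datasets, report)` with a `FilterReport`.
#' @export
rank_sum_filter <- function(datasets, frac_mean = 0.30, frac_sd = 0.30,
                            n_input_genes = NULL) {
  if (frac_mean < 0 || frac_mean >= 1 || frac_sd < 0 || frac_sd >= 1)
    stop("filter fractions must lie in [0, 1)")
  genes <- rownames(datasets[[1L]]$values)
  for (d in datasets)
    if (!identical(rownames(d$values), genes))
      stop("datasets must share an identical gene list before filtering")
  G <- length(genes)
  if (G == 0L) stop("no genes to filter")
  if (is.null(n_input_genes)) n_input_genes <- G

  rank_sums <- function(stat_by_study) {
    Reduce(`+`, lapply(stat_by_study, rank, ties.method = "average"))
  }
  subset_all <- function(keep)
    lapply(datasets, function(d)
      expression_dataset(d$values[keep, , drop = FALSE], d$group,
                         d$study_id, d$disease))

  rs_mean <- rank_sums(lapply(datasets, function(d) rowMeans(d$values)))
  n1 <- floor(frac_mean * G)
  drop1 <- genes[order(rs_mean, genes)][seq_len(n1)]
  keep1 <- setdiff(genes, drop1)
  if (!length(keep1)) stop("rank-sum filtering removed every gene")

  rs_sd <- rank_sums(lapply(datasets, function(d)
    row_sd(d$values[keep1, , drop = FALSE])))
  n2 <- floor(frac_sd * length(keep1))
  drop2 <- keep1[order(rs_sd, keep1)][seq_len(n2)]
  keep2 <- setdiff(keep1, drop2)
  if (!length(keep2)) stop("rank-sum filtering removed every gene")

  list(datasets = subset_all(keep2),
       report = filter_report(n_input_genes, G, n1, n2))
}
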
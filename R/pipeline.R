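# End-to-end orchestration: preprocess -> per-study DE -> similarity ->
# common genes -> meta-analysis (-> optional enrichment), from in-memory
# datasets (`analyze_collection`) or from a manifest on disk with persisted
# intermediates (`run_all`).

stage_call <- function(name, expr, verbose = FALSE) {
  if (verbose)
    message(sprintf("[%s] [%s] running", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Analyse a multi-study collection in memory
#'
#' Runs the full analysis chain on probe-level datasets: IQR probe
#' collapse, gene-panel intersection, rank-sum filtering, per-study
#' moderated-t differential expression, variation-profile correlation and
#' clustering, common-gene detection under both criteria, and Fisher /
#' maximum-p meta-analysis. Deterministic: no stage draws random numbers.
#'
#' @param datasets named list of probe-level [expression_dataset()]s.
#' @param probe_maps named list of probe annotation data.frames (same
#'   names as `datasets`).
#' @param study_info a [study_manifest()] or data.frame with `study_id`
#'   and `disease` (defaults to the tags carried by the datasets).
#' @param frac_mean,frac_sd rank-sum filter fractions.
#' @param k,alpha,min_diseases common-gene criteria parameters.
#' @param cor_method correlation for the similarity stage.
#' @param p_floor p-value clamp used by profiles and meta-analysis.
#' @param verbose emit stage-tagged log lines.
#' @return list of class `CrossDEAnalysis` holding every stage output.
#' @export
analyze_collection <- function(datasets, probe_maps, study_info = NULL,
                               frac_mean = 0.30, frac_sd = 0.30,
                               k = 100L, alpha = 0.01, min_diseases = 3L,
                               cor_method = "spearman", p_floor = 1e-20,
                               verbose = FALSE) {
  ids <- names(datasets)
  if (is.null(ids) || !identical(sort(ids), sort(names(probe_maps))))
    stop("'datasets' and 'probe_maps' must be named lists over the same studies")
  if (is.null(study_info))
    study_info <- data.frame(
      study_id = ids,
      disease = vapply(datasets, `[[`, "", "disease"),
      stringsAsFactors = FALSE)

  gene_level <- stage_call("collapse", lapply(ids, function(sid)
    collapse_probes_iqr(datasets[[sid]], probe_maps[[sid]])), verbose)
  names(gene_level) <- ids
  n_input <- length(unique(unlist(lapply(gene_level, function(d)
    rownames(d$values)))))

  common <- stage_call("intersect", intersect_genes(gene_level), verbose)
  names(common) <- ids

  flt <- stage_call("filter",
                    rank_sum_filter(common, frac_mean, frac_sd,
                                    n_input_genes = n_input), verbose)
  names(flt$datasets) <- ids

  de <- stage_call("diffexpr", lapply(flt$datasets, run_de), verbose)

  profiles <- stage_call("similarity", lapply(de, variation_profile,
                                              p_floor = p_floor), verbose)
  corr <- stage_call("similarity", correlation_matrix(profiles, cor_method),
                     verbose)
  tree <- stage_call("similarity", cluster_studies(corr), verbose)

  common_genes <- stage_call("common_genes", {
    hits_top <- aggregate_to_disease(make_calls(de, "top_k", k = k), study_info)
    hits_fdr <- aggregate_to_disease(make_calls(de, "fdr", alpha = alpha), study_info)
    sel_top <- select_common(hits_top, min_diseases)
    sel_fdr <- select_common(hits_fdr, min_diseases)
    list(top_k = sel_top, fdr = sel_fdr,
         union = union_criteria(sel_top, sel_fdr))
  }, verbose)

  meta <- stage_call("meta", run_meta(de, p_floor = p_floor), verbose)

  structure(list(filtered = flt$datasets, filter_report = flt$report,
                 de = de, profiles = profiles, correlation = corr,
                 tree = tree, common = common_genes, meta = meta,
                 study_info = study_info,
                 params = list(frac_mean = frac_mean, frac_sd = frac_sd,
                               k = k, alpha = alpha,
                               min_diseases = min_diseases,
                               cor_method = cor_method, p_floor = p_floor)),
            class = "CrossDEAnalysis")
}

#' @export
print.CrossDEAnalysis <- function(x, ...) {
  cat("CrossDEAnalysis over", length(x$de), "studies\n")
  print(x$filter_report)
  cat("common genes:", nrow(x$common$union), "in the union (",
      nrow(x$common$top_k), "top-k,", nrow(x$common$fdr), "fdr )\n")
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Per-study raw p-values joined onto the union gene list, so the final
# common-gene table can be audited against each study.
union_with_pvalues <- function(analysis) {
  u <- analysis$common$union
  for (sid in names(analysis$de)) {
    de <- analysis$de[[sid]]
    u[[paste0("p_", sid)]] <- de$p_value[match(u$gene, de$gene)]
  }
  m <- analysis$meta
  u$fisher_p_adj <- m$fisher_p_adj[match(u$gene, m$gene)]
  u$maxp_p_adj <- m$maxp_p_adj[match(u$gene, m$gene)]
  u
}

#' Run the full pipeline from a manifest, persisting intermediates
#'
#' Loads every study referenced by the manifest, runs
#' [analyze_collection()] and writes each stage's table under `out_dir`:
#' per-study filtered matrices and DE tables, the filter report, the
#' correlation matrix, the study dendrogram (Newick), the common-gene
#' union with per-study p-values, the meta-analysis table and, when gene
#' sets are supplied, the enrichment table. A failure in any stage aborts
#' with a stage-named error before later outputs are written.
#'
#' @param manifest a [study_manifest()] or path to a YAML manifest.
#' @param out_dir output directory (created if missing).
#' @param gene_sets optional list from [load_gene_sets()]; the union gene
#'   list is then tested against the retained-gene universe.
#' @param verbose emit stage-tagged log lines.
#' @inheritParams analyze_collection
#' @return list of class `RunReport`: parameters, output file paths,
#'   stage summary counts and package version.
#' @export
run_all <- function(manifest, out_dir, frac_mean = 0.30, frac_sd = 0.30,
                    k = 100L, alpha = 0.01, min_diseases = 3L,
                    cor_method = "spearman", p_floor = 1e-20,
                    gene_sets = NULL, verbose = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "StudyManifest"))

  loaded <- stage_call("load", lapply(manifest$entries, function(e)
    load_study(manifest, e$study_id)), verbose)
  datasets <- lapply(loaded, `[[`, "dataset")
  probe_maps <- lapply(loaded, `[[`, "probe_map")

  analysis <- analyze_collection(datasets, probe_maps,
                                 study_info = manifest,
                                 frac_mean = frac_mean, frac_sd = frac_sd,
                                 k = k, alpha = alpha,
                                 min_diseases = min_diseases,
                                 cor_method = cor_method, p_floor = p_floor,
                                 verbose = verbose)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add <- function(name, path) files[[name]] <<- path

  stage_call("write", {
    for (sid in names(analysis$filtered)) {
      add(paste0("filtered_", sid),
          write_expression_matrix(analysis$filtered[[sid]],
                                  file.path(out_dir, paste0("filtered_", sid, ".tsv")),
                                  feature_col = "gene"))
      add(paste0("de_", sid),
          write_tsv(analysis$de[[sid]],
                    file.path(out_dir, paste0("de_", sid, ".tsv"))))
    }
    fr <- analysis$filter_report
    add("filter_report",
        write_tsv(data.frame(metric = names(unclass(fr)),
                             value = unlist(unclass(fr))),
                  file.path(out_dir, "filter_report.tsv")))
    corr_df <- data.frame(study_id = rownames(analysis$correlation),
                          unclass(analysis$correlation), check.names = FALSE)
    add("correlation", write_tsv(corr_df,
        file.path(out_dir, paste0("correlation_", cor_method, ".tsv"))))
    nwk <- file.path(out_dir, "dendrogram.nwk")
    writeLines(as_newick(analysis$tree), nwk)
    add("dendrogram", nwk)
    add("common_genes", write_tsv(union_with_pvalues(analysis),
                                  file.path(out_dir, "common_genes.tsv")))
    add("meta_results", write_tsv(analysis$meta,
                                  file.path(out_dir, "meta_results.tsv")))
    if (!is.null(gene_sets) && nrow(analysis$common$union)) {
      universe <- rownames(analysis$filtered[[1L]]$values)
      add("enrichment",
          write_tsv(enrich(analysis$common$union$gene, gene_sets, universe),
                    file.path(out_dir, "enrichment.tsv")))
    }
  }, verbose)

  report <- structure(list(
    params = analysis$params,
    studies = manifest_table(manifest),
    filter_report = analysis$filter_report,
    n_significant_fdr = vapply(analysis$de, function(d)
      sum(d$p_adjusted < alpha), integer(1L)),
    n_common_union = nrow(analysis$common$union),
    files = files,
    version = as.character(utils::packageVersion("crossdeg"))),
    class = "RunReport")
  yaml::write_yaml(
    list(params = analysis$params,
         n_common_union = report$n_common_union,
         files = as.list(files), version = report$version),
    file.path(out_dir, "run_report.yaml"))
  report$analysis <- analysis
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (crossdeg", x$version, ")\n")
  print(x$filter_report)
  cat("common-gene union size:", x$n_common_union, "\n")
  cat("outputs:", length(x$files), "files\n")
  invisible(x)
}
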
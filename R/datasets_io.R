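# Readers/writers for the plain-text formats the pipeline consumes:
# expression matrices (TSV, header = sample ids, column 1 = feature id),
# probe annotation (two-column TSV), gene sets (GMT) and the study manifest
# (YAML, one block per study).

#' Construct an expression dataset
#'
#' Bundles one study's feature-by-sample log-expression matrix with its
#' case/control labels and disease tag. Features are matrix rownames
#' (probe ids before collapse, gene symbols after), samples are colnames.
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param group character vector, one of `"case"`/`"control"` per sample.
#' @param study_id short study identifier.
#' @param disease disease tag shared by all studies of that disease.
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, group, study_id, disease = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature rownames and sample colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate feature identifier(s): ", paste(head(dup, 3L), collapse = ", "))
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("'group' must label every sample (", ncol(values), " samples, ",
         length(group), " labels)")
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (sum(group == "case") < 2L || sum(group == "control") < 2L)
    stop("study '", study_id, "' needs at least 2 cases and 2 controls")
  structure(list(study_id = study_id, disease = disease,
                 values = values, group = group),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s' (%s): %d features x %d samples (%d case / %d control)\n",
              x$study_id, x$disease, nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' The file must have a header row of sample identifiers and one leading
#' feature-identifier column. Only the samples listed in `case_ids` and
#' `control_ids` are returned, in that order. Cells must parse as decimals;
#' `NA` or empty cells are a hard error (missingness is not supported).
#'
#' @param path path to the TSV file.
#' @param case_ids,control_ids sample identifiers to extract.
#' @inheritParams expression_dataset
#' @return An [expression_dataset()].
#' @export
load_expression_matrix <- function(path, case_ids, control_ids,
                                   study_id = tools::file_path_sans_ext(basename(path)),
                                   disease = NA_character_) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file has no sample columns: ", path)
  features <- raw[[1L]]
  dup <- unique(features[duplicated(features)])
  if (length(dup))
    stop("duplicate feature identifier(s) in ", path, ": ",
         paste(head(dup, 3L), collapse = ", "))
  wanted <- c(case_ids, control_ids)
  avail <- colnames(raw)[-1L]
  missing <- setdiff(wanted, avail)
  if (length(missing))
    stop("sample(s) requested but absent from ", path, ": ",
         paste(missing, collapse = ", "))
  cells <- as.matrix(raw[, wanted, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) | cells == "", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric expression value '%s' at feature '%s', sample '%s' in %s",
                 cells[bad[1L, 1L], bad[1L, 2L]], features[bad[1L, 1L]],
                 wanted[bad[1L, 2L]], path))
  dimnames(num) <- list(features, wanted)
  expression_dataset(num, c(rep("case", length(case_ids)),
                            rep("control", length(control_ids))),
                     study_id = study_id, disease = disease)
}

#' Write an expression dataset to TSV
#'
#' Values are printed with 17 significant digits (`%g`), so re-reading the
#' file reproduces them exactly.
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @param feature_col name of the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path, feature_col = "feature_id") {
  v <- dataset$values
  cm <- array(formatC(v, digits = 17L, format = "g"), dim = dim(v))
  out <- cbind(rownames(v), cm)
  colnames(out) <- c(feature_col, colnames(v))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Two-column TSV (probe_id, gene_symbol). Gene symbols are upper-cased so
#' matching is case-insensitive downstream; an empty symbol marks an
#' unannotated probe. Probe ids must be unique within a platform.
#'
#' @param path path to the annotation TSV.
#' @return data.frame with columns `probe_id`, `gene_symbol`.
#' @export
load_probe_map <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("annotation file needs two columns: ", path)
  pm <- data.frame(probe_id = raw[[1L]],
                   gene_symbol = toupper(raw[[2L]]),
                   stringsAsFactors = FALSE)
  pm$gene_symbol[is.na(pm$gene_symbol)] <- ""
  dup <- unique(pm$probe_id[duplicated(pm$probe_id)])
  if (length(dup))
    stop("duplicate probe id(s) in ", path, ": ", paste(head(dup, 3L), collapse = ", "))
  pm
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member symbols, tab-separated.
#' Members are upper-cased and de-duplicated (first occurrence kept); sets
#' are returned in file order. Blank lines are skipped.
#'
#' @param path path to the GMT file.
#' @return list of `list(name, description, genes)`.
#' @export
load_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed gene-set line ", i, " in ", path,
           " (need name, description and at least one member)")
    genes <- unique(toupper(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    sets[[length(sets) + 1L]] <- list(name = fields[[1L]],
                                      description = fields[[2L]],
                                      genes = genes)
  }
  sets
}

# ---- study manifest --------------------------------------------------------

validate_manifest_entry <- function(e, i) {
  need <- c("study_id", "disease", "case_ids", "control_ids")
  miss <- need[!need %in% names(e)]
  if (length(miss))
    stop("manifest entry ", i, " lacks field(s): ", paste(miss, collapse = ", "))
  e$case_ids <- as.character(unlist(e$case_ids))
  e$control_ids <- as.character(unlist(e$control_ids))
  if (!length(e$case_ids) || !length(e$control_ids))
    stop("study '", e$study_id, "': case and control sample lists must be non-empty")
  overlap <- intersect(e$case_ids, e$control_ids)
  if (length(overlap))
    stop("study '", e$study_id, "': sample(s) listed as both case and control: ",
         paste(head(overlap, 3L), collapse = ", "))
  e
}

#' Construct a study manifest
#'
#' A manifest maps each study to its disease, its expression and annotation
#' files, and its case/control sample identifiers.
#'
#' @param entries list of per-study lists with fields `study_id`, `disease`,
#'   `expression_path`, `annotation_path`, `case_ids`, `control_ids`.
#' @return An object of class `StudyManifest`.
#' @export
study_manifest <- function(entries) {
  entries <- lapply(seq_along(entries), function(i)
    validate_manifest_entry(entries[[i]], i))
  ids <- vapply(entries, `[[`, "", "study_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate study id(s): ", paste(dup, collapse = ", "))
  names(entries) <- ids
  structure(list(entries = entries), class = "StudyManifest")
}

#' @export
print.StudyManifest <- function(x, ...) {
  tab <- manifest_table(x)
  cat("StudyManifest with", nrow(tab), "studies over",
      length(unique(tab$disease)), "diseases\n")
  print(tab)
  invisible(x)
}

#' Summarise a manifest as a data frame
#'
#' @param manifest a [study_manifest()].
#' @return data.frame with one row per study.
#' @export
manifest_table <- function(manifest) {
  do.call(rbind, lapply(manifest$entries, function(e)
    data.frame(study_id = e$study_id, disease = e$disease,
               n_case = length(e$case_ids), n_control = length(e$control_ids),
               stringsAsFactors = FALSE)))
}

#' Read a study manifest from YAML
#'
#' Relative `expression_path`/`annotation_path` entries are resolved against
#' the manifest's own directory.
#'
#' @param path path to the YAML manifest.
#' @return A [study_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$studies)) stop("manifest has no 'studies' block: ", path)
  base <- dirname(normalizePath(path))
  entries <- lapply(y$studies, function(e) {
    for (f in c("expression_path", "annotation_path")) {
      if (!is.null(e[[f]]) && !grepl("^(/|[A-Za-z]:)", e[[f]]))
        e[[f]] <- file.path(base, e[[f]])
    }
    e
  })
  study_manifest(entries)
}

#' Write a study manifest to YAML
#'
#' @param manifest a [study_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(list(studies = unname(manifest$entries)), path)
  invisible(path)
}

#' Load one study's expression data and probe map from a manifest
#'
#' @param manifest a [study_manifest()].
#' @param study_id which study to load.
#' @return `list(dataset, probe_map)`.
#' @export
load_study <- function(manifest, study_id) {
  e <- manifest$entries[[study_id]]
  if (is.null(e)) stop("study '", study_id, "' not in manifest")
  dataset <- load_expression_matrix(e$expression_path, e$case_ids, e$control_ids,
                                    study_id = e$study_id, disease = e$disease)
  list(dataset = dataset, probe_map = load_probe_map(e$annotation_path))
}
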
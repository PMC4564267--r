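# Seeded simulator for multi-study, multi-disease expression collections
# with a known truth, so every pipeline stage (probe collapse, panel
# intersection, filtering, DE, similarity, common-gene detection, meta-
# analysis) can be validated without any external download.
#
# Model: per gene g a variance sigma_g^2 is drawn from the scaled
# inverse-chi-square prior s0^2 * d0 / chisq(d0) that the moderated-t
# machinery assumes; control samples are Normal(baseline_g, sigma_g^2) on
# the log-intensity scale and cases of affected diseases are shifted by
# delta * sigma_g with a per-gene sign. Probes of a gene are the gene
# signal plus a constant probe offset and small additive noise; platforms
# profile overlapping gene subsets; "dead" genes get minimal baseline and
# variance so the rank-sum filter has something to remove.

#' Default study design
#'
#' Six blood case/control datasets over four rheumatic diseases
#' (rheumatoid arthritis, systemic lupus erythematosus, osteoarthritis,
#' ankylosing spondylitis) on four array platforms, with the sample sizes
#' of the public GEO series the pipeline was designed around.
#'
#' @return data.frame with `study_id`, `disease`, `platform`, `n_case`,
#'   `n_control`.
#' @export
sim_study_defaults <- function() {
  data.frame(
    study_id  = c("RA1", "RA2", "SLE1", "SLE2", "OA", "AS"),
    disease   = c("RA", "RA", "SLE", "SLE", "OA", "AS"),
    platform  = c("GPLa", "GPLb", "GPLc", "GPLc", "GPLd", "GPLd"),
    n_case    = c(18L, 20L, 11L, 21L, 106L, 16L),
    n_control = c(15L, 11L, 6L, 45L, 33L, 16L),
    stringsAsFactors = FALSE)
}

#' Default planted effect sets
#'
#' One set of shared markers affecting three of the four diseases (the
#' signal the common-gene stage must recover) plus one disease-specific
#' signature per disease (what makes same-disease datasets resemble each
#' other more than cross-disease pairs).
#'
#' @param delta effect size in units of the gene's own standard deviation.
#' @return list of `list(n, diseases, delta)`.
#' @export
default_planted <- function(delta = 1.5) {
  list(list(n = 25L, diseases = c("RA", "SLE", "AS"), delta = delta),
       list(n = 40L, diseases = "RA",  delta = delta),
       list(n = 40L, diseases = "SLE", delta = delta),
       list(n = 40L, diseases = "OA",  delta = delta),
       list(n = 40L, diseases = "AS",  delta = delta))
}

#' Simulation configuration
#'
#' @param studies study design data.frame, see [sim_study_defaults()].
#' @param n_genes total genes in the simulated genome.
#' @param probes_per_gene integer vector sampled uniformly per gene.
#' @param platform_overlap fraction of null genes each platform profiles;
#'   planted and dead genes sit on every platform (shared markers must be
#'   commonly profiled to be discoverable at all).
#' @param prior_df,prior_var scaled inverse-chi-square variance prior
#'   (d0, s0^2).
#' @param planted list of planted effect sets, see [default_planted()].
#' @param dead_genes number of un-expressed, near-constant genes.
#' @param baseline_mean,baseline_sd log-intensity baseline distribution.
#' @param probe_offset_sd sd of the constant per-probe offset.
#' @param probe_noise_sd sd of the per-cell probe noise (kept small so the
#'   observed gene variance stays close to sigma_g^2).
#' @param n_unannotated junk probes without a gene symbol, per platform.
#' @param effect_sign `"shared"` fixes one sign per gene across diseases;
#'   `"mixed"` redraws the sign per disease.
#' @param seed mandatory RNG seed.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(studies = sim_study_defaults(),
                       n_genes = 3000L,
                       probes_per_gene = 1:3,
                       platform_overlap = 0.85,
                       prior_df = 4,
                       prior_var = 0.05,
                       planted = default_planted(),
                       dead_genes = 150L,
                       baseline_mean = 7,
                       baseline_sd = 1,
                       probe_offset_sd = 0.3,
                       probe_noise_sd = 0.05,
                       n_unannotated = 25L,
                       effect_sign = c("shared", "mixed"),
                       seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  effect_sign <- match.arg(effect_sign)
  if (n_genes < 1L || any(probes_per_gene < 1L))
    stop("gene and probe counts must be positive")
  if (platform_overlap <= 0 || platform_overlap > 1)
    stop("'platform_overlap' must lie in (0, 1]")
  if (prior_df <= 0 || prior_var <= 0) stop("variance prior must be positive")
  n_planted <- sum(vapply(planted, function(s) as.integer(s$n), integer(1L)))
  for (s in planted) {
    if (s$delta < 0) stop("planted effect sizes must be >= 0")
    bad <- setdiff(s$diseases, studies$disease)
    if (length(bad))
      stop("planted set names unknown disease(s): ", paste(bad, collapse = ", "))
  }
  if (n_planted + dead_genes > n_genes)
    stop("planted plus dead genes exceed n_genes")
  structure(list(studies = studies, n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 platform_overlap = platform_overlap,
                 prior_df = prior_df, prior_var = prior_var,
                 planted = planted, dead_genes = as.integer(dead_genes),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 probe_offset_sd = probe_offset_sd,
                 probe_noise_sd = probe_noise_sd,
                 n_unannotated = as.integer(n_unannotated),
                 effect_sign = effect_sign, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Generate a simulated multi-study collection
#'
#' All draws come from one generator seeded with `config$seed`, so an
#' identical configuration reproduces the collection exactly.
#'
#' Planted marker genes draw their baselines and variances from the upper
#' ~60% of the null distributions: real disease signatures are, by
#' construction of the filtering step they must survive, expressed and
#' informative transcripts. Dead genes sit at a low baseline with
#' near-zero variance.
#'
#' @param config a [sim_config()].
#' @return list of class `StudyCollection` with `manifest` (paths unset
#'   until [write_collection()]), `datasets` (probe-level, named by
#'   study), `probe_maps` (named by study), `truth` (per-gene status,
#'   affected diseases, effect and sign) and `config`.
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  st <- config$studies
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  diseases <- unique(st$disease)

  # --- assign gene roles ----------------------------------------------------
  shuffled <- sample(genes)
  cursor <- 0L
  take <- function(m) {
    out <- shuffled[cursor + seq_len(m)]
    cursor <<- cursor + m
    out
  }
  dead <- take(config$dead_genes)
  planted_sets <- lapply(config$planted, function(s) {
    s$genes <- take(as.integer(s$n)); s
  })
  planted_all <- unlist(lapply(planted_sets, `[[`, "genes"), use.names = FALSE)

  # --- per-gene parameters --------------------------------------------------
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  sigma2 <- config$prior_var * config$prior_df / stats::rchisq(n, config$prior_df)
  names(baseline) <- names(sigma2) <- genes
  if (length(planted_all)) {
    np <- length(planted_all)
    baseline[planted_all] <- stats::qnorm(stats::runif(np, 0.40, 0.999),
                                          config$baseline_mean, config$baseline_sd)
    sigma2[planted_all] <- config$prior_var * config$prior_df /
      stats::qchisq(stats::runif(np, 0.02, 0.60), config$prior_df)
  }
  if (length(dead)) {
    baseline[dead] <- stats::rnorm(length(dead), 4, 0.3)
    sigma2[dead] <- 0.002 * config$prior_df / stats::rchisq(length(dead), config$prior_df)
  }
  sign_g <- sample(c(-1, 1), n, replace = TRUE)
  names(sign_g) <- genes

  # signed effect (in sigma units) per gene x disease
  delta_mat <- matrix(0, n, length(diseases), dimnames = list(genes, diseases))
  for (s in planted_sets) {
    for (dz in s$diseases) {
      sgn <- if (config$effect_sign == "shared") sign_g[s$genes]
             else sample(c(-1, 1), length(s$genes), replace = TRUE)
      delta_mat[s$genes, dz] <- s$delta * sgn
    }
  }

  # --- platforms: gene panels and probe maps --------------------------------
  platforms <- unique(st$platform)
  guaranteed <- c(planted_all, dead)
  nulls <- setdiff(genes, guaranteed)
  panels <- list(); probe_tabs <- list()
  for (pl in platforms) {
    panel <- sort_c(c(guaranteed,
                      sample(nulls, floor(config$platform_overlap * length(nulls)))))
    n_probes <- if (length(config$probes_per_gene) == 1L)
      rep(config$probes_per_gene, length(panel))
    else sample(config$probes_per_gene, length(panel), replace = TRUE)
    gene_of_probe <- rep(panel, n_probes)
    n_ann <- length(gene_of_probe)
    tab <- data.frame(
      probe_id = sprintf("%s_%06d", pl, seq_len(n_ann + config$n_unannotated)),
      gene = c(gene_of_probe, rep("", config$n_unannotated)),
      offset = c(stats::rnorm(n_ann, 0, config$probe_offset_sd),
                 rep(0, config$n_unannotated)),
      stringsAsFactors = FALSE)
    tab$gene_idx <- match(tab$gene, panel)           # NA for unannotated
    tab$junk_baseline <- c(rep(NA_real_, n_ann),
                           stats::rnorm(config$n_unannotated,
                                        config$baseline_mean, config$baseline_sd))
    panels[[pl]] <- panel
    probe_tabs[[pl]] <- tab
  }

  # --- per-study data -------------------------------------------------------
  datasets <- list(); probe_maps <- list(); entries <- list()
  for (i in seq_len(nrow(st))) {
    sid <- st$study_id[[i]]; dz <- st$disease[[i]]; pl <- st$platform[[i]]
    n1 <- st$n_case[[i]]; n2 <- st$n_control[[i]]
    samples <- c(sprintf("%s_case_%03d", sid, seq_len(n1)),
                 sprintf("%s_ctrl_%03d", sid, seq_len(n2)))
    group <- c(rep("case", n1), rep("control", n2))
    panel <- panels[[pl]]; tab <- probe_tabs[[pl]]
    Gp <- length(panel); S <- n1 + n2
    sd_g <- sqrt(sigma2[panel])
    Z <- baseline[panel] + sd_g * matrix(stats::rnorm(Gp * S), Gp, S)
    shift <- delta_mat[panel, dz] * sd_g
    Z[, seq_len(n1)] <- Z[, seq_len(n1)] + shift
    ann <- !is.na(tab$gene_idx)
    V <- matrix(0, nrow(tab), S)
    V[ann, ] <- Z[tab$gene_idx[ann], , drop = FALSE] + tab$offset[ann] +
      matrix(stats::rnorm(sum(ann) * S, 0, config$probe_noise_sd), sum(ann), S)
    if (any(!ann))
      V[!ann, ] <- tab$junk_baseline[!ann] +
        matrix(stats::rnorm(sum(!ann) * S, 0, 0.3), sum(!ann), S)
    dimnames(V) <- list(tab$probe_id, samples)
    datasets[[sid]] <- expression_dataset(V, group, sid, dz)
    probe_maps[[sid]] <- data.frame(probe_id = tab$probe_id,
                                    gene_symbol = tab$gene,
                                    stringsAsFactors = FALSE)
    entries[[sid]] <- list(study_id = sid, disease = dz,
                           platform = pl,
                           expression_path = NA_character_,
                           annotation_path = NA_character_,
                           case_ids = samples[seq_len(n1)],
                           control_ids = samples[n1 + seq_len(n2)])
  }

  # --- truth ----------------------------------------------------------------
  affected <- apply(delta_mat != 0, 1L, function(row)
    paste(sort(colnames(delta_mat)[row], method = "radix"), collapse = ","))
  truth <- data.frame(
    gene = genes,
    status = ifelse(genes %in% dead, "dead",
                    ifelse(genes %in% planted_all, "planted", "null")),
    diseases = affected,
    n_diseases = rowSums(delta_mat != 0),
    effect = apply(abs(delta_mat), 1L, max),
    sign = ifelse(genes %in% planted_all, sign_g, 0),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(manifest = study_manifest(entries), datasets = datasets,
                 probe_maps = probe_maps, truth = truth, config = config),
            class = "StudyCollection")
}

#' Genes planted in at least `min_diseases` diseases
#'
#' @param truth the `truth` table of a [generate_collection()] result.
#' @param min_diseases disease-count threshold.
#' @return character vector of gene symbols.
#' @export
truth_common_genes <- function(truth, min_diseases = 3L) {
  truth$gene[truth$status == "planted" & truth$n_diseases >= min_diseases]
}

#' Write a simulated collection to disk
#'
#' Emits, under `dir`, one probe-level expression TSV per study, one
#' annotation TSV per platform and a YAML manifest referencing them with
#' relative paths — the same dialect the loaders read back.
#'
#' @param collection a [generate_collection()] result.
#' @param dir output directory (created if missing).
#' @return path to the written manifest, invisibly.
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "StudyCollection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- collection$manifest$entries
  written_platform <- character()
  for (sid in names(collection$datasets)) {
    expr_file <- paste0(sid, "_expr.tsv")
    write_expression_matrix(collection$datasets[[sid]],
                            file.path(dir, expr_file),
                            feature_col = "probe_id")
    pl <- entries[[sid]]$platform
    ann_file <- paste0(pl, "_annotation.tsv")
    if (!pl %in% written_platform) {
      utils::write.table(collection$probe_maps[[sid]],
                         file.path(dir, ann_file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      written_platform <- c(written_platform, pl)
    }
    entries[[sid]]$expression_path <- expr_file
    entries[[sid]]$annotation_path <- ann_file
  }
  manifest_path <- file.path(dir, "manifest.yaml")
  write_manifest(study_manifest(entries), manifest_path)
  invisible(manifest_path)
}
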
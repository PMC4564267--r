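# Small in-code fixtures shared across test files.

# Feature-by-sample dataset from a matrix of values given by row.
make_dataset <- function(values, n_case, n_control, study_id = "S1",
                         disease = "D1", features = NULL) {
  m <- matrix(values, ncol = n_case + n_control, byrow = TRUE)
  if (is.null(features)) features <- sprintf("G%02d", seq_len(nrow(m)))
  rownames(m) <- features
  colnames(m) <- c(sprintf("c%02d", seq_len(n_case)),
                   sprintf("n%02d", seq_len(n_control)))
  expression_dataset(m, c(rep("case", n_case), rep("control", n_control)),
                     study_id, disease)
}

# Pure-noise dataset for null-behaviour checks.
null_dataset <- function(n_genes, n_case, n_control, study_id = "S1",
                         disease = "D1") {
  m <- matrix(rnorm(n_genes * (n_case + n_control), 7, 0.5), nrow = n_genes)
  rownames(m) <- sprintf("G%04d", seq_len(n_genes))
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  expression_dataset(m, c(rep("case", n_case), rep("control", n_control)),
                     study_id, disease)
}

# Down-scaled simulator configuration for property tests. Arguments are
# forwarded explicitly (never merged), so list-valued overrides such as
# `planted = list()` really replace the defaults.
tiny_sim_config <- function(seed,
                            n_genes = 400L,
                            probes_per_gene = 1:2,
                            platform_overlap = 0.9,
                            dead_genes = 40L,
                            n_unannotated = 5L,
                            planted = list(
                              list(n = 15L, diseases = c("DA", "DB"), delta = 1.5),
                              list(n = 15L, diseases = "DA", delta = 1.5),
                              list(n = 15L, diseases = "DB", delta = 1.5)),
                            probe_noise_sd = 0.05,
                            probe_offset_sd = 0.3) {
  studies <- data.frame(
    study_id = c("A1", "A2", "B1", "B2"),
    disease = c("DA", "DA", "DB", "DB"),
    platform = c("P1", "P1", "P2", "P2"),
    n_case = c(10L, 12L, 10L, 14L),
    n_control = c(10L, 8L, 10L, 12L),
    stringsAsFactors = FALSE)
  sim_config(studies = studies, n_genes = n_genes,
             probes_per_gene = probes_per_gene,
             platform_overlap = platform_overlap,
             dead_genes = dead_genes, n_unannotated = n_unannotated,
             planted = planted, probe_noise_sd = probe_noise_sd,
             probe_offset_sd = probe_offset_sd, seed = seed)
}

# Minimal DEResult-shaped table for stages that only need t/p/rank.
fake_de <- function(t, p, genes = sprintf("G%02d", seq_along(t)),
                    study_id = "S1") {
  res <- data.frame(gene = genes, t = t, df_total = 10, p_value = p,
                    p_adjusted = pmin(p * 2, 1),
                    rank = rank(p, ties.method = "first"),
                    stringsAsFactors = FALSE)
  attr(res, "study_id") <- study_id
  res
}

are_siblings_test <- function(hc, a, b) crossdeg:::are_siblings(hc, a, b)

# The example cross-study significance pattern shipped with the package
# (ten blood-expression marker genes over six rheumatic-disease datasets).
example_calls <- function() {
  read.delim(system.file("extdata", "example_significance_calls.tsv",
                         package = "crossdeg"),
             stringsAsFactors = FALSE)
}

example_study_info <- function() {
  data.frame(study_id = c("RA1", "RA2", "SLE1", "SLE2", "OA", "AS"),
             disease = c("RA", "RA", "SLE", "SLE", "OA", "AS"),
             stringsAsFactors = FALSE)
}
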
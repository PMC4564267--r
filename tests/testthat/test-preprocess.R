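test_that("probe collapse keeps the largest-IQR probe per gene", {
  ds <- make_dataset(c(1, 2, 3, 4,
                       0, 10, 0, 10,
                       5, 5, 5, 5), 2, 2, features = c("P1", "P2", "P3"))
  pm <- data.frame(probe_id = c("P1", "P2", "P3"),
                   gene_symbol = c("G", "G", "H"))
  out <- collapse_probes_iqr(ds, pm)
  # IQR(P1) = 1.5, IQR(P2) = 10 under type-7 quartiles -> keep P2's row
  expect_equal(unname(out$values["G", ]), c(0, 10, 0, 10))
  # single-probe gene passes through unchanged
  expect_equal(unname(out$values["H", ]), c(5, 5, 5, 5))
  # each output row is literally one input row
  for (g in rownames(out$values))
    expect_true(any(apply(ds$values, 1, identical, out$values[g, ])))
})

test_that("probe collapse breaks IQR ties by file order and drops unannotated", {
  ds <- make_dataset(c(1, 2, 3, 4,
                       4, 3, 2, 1,
                       9, 9, 9, 9), 2, 2, features = c("Pa", "Pb", "Pjunk"))
  pm <- data.frame(probe_id = c("Pa", "Pb", "Pjunk"),
                   gene_symbol = c("G", "G", ""))
  out <- collapse_probes_iqr(ds, pm)
  expect_identical(rownames(out$values), "G")
  expect_equal(unname(out$values["G", ]), c(1, 2, 3, 4))  # Pa came first

  pm_none <- data.frame(probe_id = "Pz", gene_symbol = "G")
  expect_error(collapse_probes_iqr(ds, pm_none), "no probe maps")
})

test_that("gene-panel intersection restricts to shared genes in one order", {
  mk <- function(genes, sid) {
    m <- matrix(seq_along(genes), nrow = length(genes), ncol = 4)
    dimnames(m) <- list(genes, sprintf("%s_s%d", sid, 1:4))
    expression_dataset(m, c("case", "case", "control", "control"), sid)
  }
  out <- intersect_genes(list(mk(c("A", "B", "C"), "S1"),
                              mk(c("B", "C", "D"), "S2"),
                              mk(c("C", "B"), "S3")))
  for (d in out) expect_identical(rownames(d$values), c("B", "C"))

  same <- intersect_genes(list(mk(c("B", "A"), "S1"), mk(c("A", "B"), "S2")))
  expect_identical(rownames(same[[1]]$values), c("A", "B"))

  expect_error(intersect_genes(list(mk(c("A", "B"), "S1"), mk(c("C", "D"), "S2"))),
               "no genes")
})

test_that("rank-sum filtering removes floor-based counts in two stages", {
  set.seed(1)
  ds <- list(null_dataset(10, 3, 3, "S1"), null_dataset(10, 3, 3, "S2"))
  out <- rank_sum_filter(ds, 0.30, 0.30)
  expect_identical(out$report$n_removed_unexpressed, 3)    # floor(0.3*10)
  expect_identical(out$report$n_removed_uninformative, 2)  # floor(0.3*7)
  expect_identical(out$report$n_retained, 5)
  expect_identical(nrow(out$datasets[[1]]$values), 5L)

  # zero fractions: identity
  out0 <- rank_sum_filter(ds, 0, 0)
  expect_equal(out0$datasets[[1]]$values, ds[[1]]$values)
  expect_identical(out0$report$n_removed_unexpressed, 0)
  expect_identical(out0$report$n_removed_uninformative, 0)

  expect_error(rank_sum_filter(ds, 1, 0), "fractions")
})

test_that("stage-1 removal targets the smallest mean rank sums exactly", {
  # hand-set means: per-dataset gene means 1..4 in the same order, so
  # rank sums are (2, 4, 6, 8); frac 0.25 removes exactly the first gene
  mk <- function(sid) {
    m <- matrix(rep(c(1, 2, 3, 4), each = 4), nrow = 4, byrow = TRUE)
    m <- m + matrix(c(-0.1, 0.1, -0.1, 0.1), nrow = 4, ncol = 4, byrow = TRUE)
    dimnames(m) <- list(c("GA", "GB", "GC", "GD"), sprintf("%s_s%d", sid, 1:4))
    expression_dataset(m, c("case", "case", "control", "control"), sid)
  }
  out <- rank_sum_filter(list(mk("S1"), mk("S2")), frac_mean = 0.25, frac_sd = 0)
  expect_identical(rownames(out$datasets[[1]]$values), c("GB", "GC", "GD"))
})

test_that("rank-sum filtering is permutation-equivariant", {
  set.seed(7)
  ds <- list(null_dataset(30, 4, 4, "S1"), null_dataset(30, 4, 4, "S2"))
  perm <- sample(30)
  ds_perm <- lapply(ds, function(d)
    expression_dataset(d$values[perm, , drop = FALSE], d$group,
                       d$study_id, d$disease))
  a <- rank_sum_filter(ds, 0.3, 0.3)$datasets[[1]]
  b <- rank_sum_filter(ds_perm, 0.3, 0.3)$datasets[[1]]
  expect_setequal(rownames(a$values), rownames(b$values))
  common <- sort(rownames(a$values))
  expect_equal(a$values[common, ], b$values[common, ])
})

test_that("planted dead genes are removed at the default fractions", {
  col <- generate_collection(tiny_sim_config(seed = 3))
  gene_level <- mapply(collapse_probes_iqr, col$datasets, col$probe_maps,
                       SIMPLIFY = FALSE)
  common <- intersect_genes(gene_level)
  flt <- rank_sum_filter(common)
  dead <- col$truth$gene[col$truth$status == "dead"]
  expect_length(intersect(rownames(flt$datasets[[1]]$values), dead), 0L)
})
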
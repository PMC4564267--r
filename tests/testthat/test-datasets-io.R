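write_tsv_fixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "expr.tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("expression matrices read back with manifest sample selection", {
  df <- data.frame(probe_id = c("P1", "P2", "P3"),
                   s1 = c(1.5, 2, 3), s2 = c(4, 5, 6),
                   s3 = c(7, 8, 9), s4 = c(10, 11, 12.25))
  path <- write_tsv_fixture(df)

  ds <- load_expression_matrix(path, case_ids = c("s1", "s2"),
                               control_ids = c("s3", "s4"),
                               study_id = "S1", disease = "D")
  expect_equal(dim(ds$values), c(3L, 4L))
  expect_identical(rownames(ds$values), c("P1", "P2", "P3"))
  expect_identical(ds$group, c("case", "case", "control", "control"))
  expect_equal(unname(ds$values["P3", ]), c(3, 6, 9, 12.25))

  # manifest requesting a subset reorders columns to manifest order
  ds2 <- load_expression_matrix(path, case_ids = c("s4", "s2"),
                                control_ids = c("s1", "s3"))
  expect_identical(colnames(ds2$values), c("s4", "s2", "s1", "s3"))
  expect_equal(unname(ds2$values["P1", ]), c(10, 4, 1.5, 7))
})

test_that("malformed expression input is a named hard error", {
  df <- data.frame(probe_id = c("P1", "P2"), s1 = 1:2, s2 = 3:4,
                   s3 = 5:6, s4 = 7:8)
  path <- write_tsv_fixture(df)
  expect_error(load_expression_matrix(path, c("s1", "sX"), c("s3", "s4")),
               "sX")

  df_bad <- df; df_bad$s2 <- c("3", "oops")
  path2 <- write_tsv_fixture(df_bad)
  expect_error(load_expression_matrix(path2, c("s1", "s2"), c("s3", "s4")),
               "P2.*s2")

  df_dup <- df; df_dup$probe_id <- c("P1", "P1")
  path3 <- write_tsv_fixture(df_dup)
  expect_error(load_expression_matrix(path3, c("s1", "s2"), c("s3", "s4")),
               "duplicate feature")

  df_na <- df; df_na$s1 <- c("1", "NA")
  path4 <- write_tsv_fixture(df_na)
  expect_error(load_expression_matrix(path4, c("s1", "s2"), c("s3", "s4")),
               "non-numeric")
})

test_that("write/read round trip preserves values and ordering exactly", {
  set.seed(11)
  ds <- null_dataset(20, 3, 3, study_id = "RT")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rt.tsv")
  write_expression_matrix(ds, path)
  back <- load_expression_matrix(path, case_ids = colnames(ds$values)[1:3],
                                 control_ids = colnames(ds$values)[4:6])
  expect_identical(rownames(back$values), rownames(ds$values))
  expect_identical(colnames(back$values), colnames(ds$values))
  expect_equal(back$values, ds$values, tolerance = 0)
})

test_that("GMT gene sets parse, de-duplicate and keep file order", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines(c("GO_X\tdesc\tA\tb\tA", "GO_Y\tother\tC\tD"), path)
  sets <- load_gene_sets(path)
  expect_length(sets, 2L)
  expect_identical(sets[[1]]$name, "GO_X")
  expect_identical(sets[[1]]$genes, c("A", "B"))
  expect_identical(sets[[2]]$genes, c("C", "D"))

  writeLines("GO_Y\tdesc", path)
  expect_error(load_gene_sets(path), "line 1")
})

test_that("manifests validate, round-trip through YAML and resolve paths", {
  entries <- list(
    list(study_id = "S1", disease = "D1", expression_path = "s1.tsv",
         annotation_path = "ann.tsv", case_ids = c("a", "b"),
         control_ids = c("c", "d")),
    list(study_id = "S2", disease = "D1", expression_path = "s2.tsv",
         annotation_path = "ann.tsv", case_ids = "e", control_ids = "f"))
  mf <- study_manifest(entries)
  expect_identical(names(mf$entries), c("S1", "S2"))

  dir <- withr::local_tempdir()
  path <- file.path(dir, "manifest.yaml")
  write_manifest(mf, path)
  back <- read_manifest(path)
  expect_identical(manifest_table(back)$study_id, c("S1", "S2"))
  # relative paths resolved against the manifest directory
  expect_true(startsWith(back$entries$S1$expression_path, normalizePath(dir)))

  entries_dup <- entries
  entries_dup[[2]]$study_id <- "S1"
  expect_error(study_manifest(entries_dup), "duplicate study")

  entries_bad <- entries
  entries_bad[[1]]$control_ids <- c("a", "d")
  expect_error(study_manifest(entries_bad), "both case and control")

  entries_empty <- entries
  entries_empty[[1]]$case_ids <- character()
  expect_error(study_manifest(entries_empty), "non-empty")
})
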
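test_that("per-gene summaries match hand computation", {
  ds <- make_dataset(c(2, 4, 1, 1,
                       5, 5, 5, 5,
                       3, 3, 1, 5), 2, 2)
  sm <- summarize_genes(ds)
  # cases (2,4), controls (1,1): M = 2, pooled s^2 = (2+0)/2 = 1, d = 2, v = 1
  expect_equal(sm$mean_diff[1], 2)
  expect_equal(sm$pooled_var[1], 1)
  expect_equal(sm$df[1], 2L)
  expect_equal(sm$v[1], 1)
  # identical case/control values: M = 0; constant gene: s^2 = 0
  expect_equal(sm$mean_diff[2], 0)
  expect_equal(sm$pooled_var[2], 0)
  # spread only among controls (1, 5): pooled s^2 = (0 + 8)/2 = 4
  expect_equal(sm$pooled_var[3], 4)

  one_case <- matrix(1:8, 2, 4,
                     dimnames = list(c("a", "b"), sprintf("s%d", 1:4)))
  expect_error(expression_dataset(one_case, c("case", "control", "control",
                                              "control"), "X"),
               "at least 2")
})

test_that("trigamma inversion recovers its argument", {
  for (x in c(0.1, 0.5, 2.0, 10, 250))
    expect_equal(trigamma_inverse(trigamma(x)), x, tolerance = 1e-8)
  expect_error(trigamma_inverse(-1), "> 0")
})

test_that("hyperparameter estimation recovers a known variance prior", {
  set.seed(42)
  G <- 5000; d0 <- 4; s0 <- 0.05; d <- 10
  sigma2 <- s0 * d0 / rchisq(G, d0)
  s2 <- sigma2 * rchisq(G, d) / d
  sm <- data.frame(gene = sprintf("G%04d", 1:G), mean_diff = 0,
                   pooled_var = s2, df = d, v = 0.2)
  hp <- estimate_hyperparams(sm)
  expect_lt(abs(hp$prior_df - d0) / d0, 0.2)
  expect_lt(abs(hp$prior_var - s0) / s0, 0.2)
})

test_that("degenerate and undersized hyperparameter inputs are handled", {
  sm_equal <- data.frame(gene = sprintf("G%02d", 1:20), mean_diff = 0,
                         pooled_var = 0.3, df = 10, v = 0.2)
  hp <- estimate_hyperparams(sm_equal)
  expect_identical(hp$prior_df, Inf)
  expect_gt(hp$prior_var, 0)

  sm_few <- data.frame(gene = c("A", "B"), mean_diff = 0,
                       pooled_var = c(0.1, 0.2), df = 4, v = 0.5)
  expect_error(estimate_hyperparams(sm_few), "at least 10")
})

test_that("moderated t matches hand computation and its limits", {
  sm <- data.frame(gene = "G1", mean_diff = 1, pooled_var = 0.5,
                   df = 4, v = 0.2)
  mt <- moderated_t(sm, list(prior_df = 4, prior_var = 1))
  # s~^2 = (4*1 + 4*0.5)/8 = 0.75; t = 1/sqrt(0.15); df = 8
  expect_equal(mt$t, 1 / sqrt(0.15), tolerance = 1e-12)
  expect_equal(mt$df_total, 8)
  expect_equal(mt$p_value, 2 * pt(-1 / sqrt(0.15), 8), tolerance = 1e-12)

  # M = 0 -> t = 0, p = 1
  sm0 <- transform(sm, mean_diff = 0)
  mt0 <- moderated_t(sm0, list(prior_df = 4, prior_var = 1))
  expect_equal(mt0$t, 0)
  expect_equal(mt0$p_value, 1)

  # infinite prior df: normal reference
  mtI <- moderated_t(sm, list(prior_df = Inf, prior_var = 0.5))
  expect_equal(mtI$t, 1 / sqrt(0.1), tolerance = 1e-12)
  expect_equal(mtI$p_value, 2 * pnorm(-1 / sqrt(0.1)), tolerance = 1e-12)
})

test_that("with zero prior df the pipeline equals the ordinary pooled t-test", {
  set.seed(5)
  ds <- null_dataset(40, 5, 5)
  sm <- summarize_genes(ds)
  mt <- moderated_t(sm, list(prior_df = 0, prior_var = 1))
  oracle <- pooled_t_oracle(ds)
  expect_equal(mt$t, unname(oracle[, "t"]), tolerance = 1e-10)
  expect_equal(mt$p_value, unname(oracle[, "p"]), tolerance = 1e-10)
})

test_that("|moderated t| decreases as the prior variance grows", {
  sm <- data.frame(gene = "G1", mean_diff = 1.3, pooled_var = 0.4,
                   df = 6, v = 0.3)
  t_abs <- vapply(c(0.1, 0.5, 1, 5, 20), function(s0)
    abs(moderated_t(sm, list(prior_df = 4, prior_var = s0))$t), numeric(1))
  expect_true(all(diff(t_abs) < 0))
})

test_that("BH adjustment matches the step-up definition and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\(0, 1\\]")

  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(2:80, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # preserves p ordering
  }
})

test_that("DE results rank deterministically and cross-check against limma", {
  set.seed(13)
  # gene-specific variances from the inverse-chi-square prior, so the
  # prior df estimate is finite and the empirical-Bayes fit is exercised
  sigma <- sqrt(0.05 * 4 / rchisq(200, 4))
  m <- 7 + matrix(rnorm(200 * 12), 200, 12) * sigma
  dimnames(m) <- list(sprintf("G%04d", 1:200), sprintf("s%03d", 1:12))
  ds <- expression_dataset(m, rep(c("case", "control"), each = 6), "S1", "D1")
  de <- run_de(ds)
  expect_setequal(de$rank, seq_len(200))
  expect_identical(de$gene[order(de$rank)][1], de$gene[which.min(de$p_value)])
  expect_true(all(de$p_adjusted >= de$p_value))

  skip_if_not_installed("limma")
  design <- cbind(1, as.integer(ds$group == "case"))
  fit <- limma::eBayes(limma::lmFit(ds$values, design))
  hp <- attr(de, "hyperparams")
  expect_true(is.finite(hp$prior_df))
  expect_equal(hp$prior_df, fit$df.prior, tolerance = 1e-6)
  expect_equal(hp$prior_var, fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, fit$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(de$p_value, fit$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("under a global null the BH discovery fraction is controlled", {
  set.seed(2024)
  frac <- replicate(30, {
    de <- run_de(null_dataset(400, 8, 8))
    mean(de$p_adjusted < 0.05)
  })
  # expectation <= 0.05; allow two Monte-Carlo standard errors
  expect_lte(mean(frac), 0.05 + 2 * sd(frac) / sqrt(length(frac)))
})
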
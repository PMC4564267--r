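# Per-study differential expression with an empirical-Bayes moderated
# t-statistic. The gene-wise pooled variance s_g^2 (d_g residual df) is
# shrunk toward a prior s0^2 with d0 prior df; (d0, s0^2) are estimated by
# the closed-form moment method on log variances, with the inverse
# trigamma solved by Newton iteration.

#' Per-gene two-group summaries
#'
#' Computes, for every gene, the case-minus-control mean difference, the
#' pooled within-group variance with `n1 + n2 - 2` residual degrees of
#' freedom, and the design factor `v = 1/n1 + 1/n2`.
#'
#' @param dataset an [expression_dataset()] with >= 2 cases and controls.
#' @return data.frame with columns `gene`, `mean_diff`, `pooled_var`,
#'   `df`, `v`.
#' @export
summarize_genes <- function(dataset) {
  is_case <- dataset$group == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (", n1, " cases, ", n2, " controls)")
  x1 <- dataset$values[, is_case, drop = FALSE]
  x2 <- dataset$values[, !is_case, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  d <- n1 + n2 - 2L
  data.frame(gene = rownames(dataset$values),
             mean_diff = m1 - m2,
             pooled_var = (ss1 + ss2) / d,
             df = d,
             v = 1 / n1 + 1 / n2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by monotone Newton iteration on
#' `1/trigamma`, which is nearly linear.
#'
#' @param y positive target value.
#' @return The solution `x`.
#' @export
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) stop("trigamma_inverse requires a finite y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (it in seq_len(100L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-12 * x) break
  }
  x
}

#' Estimate the variance-prior hyperparameters
#'
#' Moment estimation on log variances: with `z_g = ln s_g^2` and
#' `e_g = z_g - digamma(d_g/2) + ln(d_g/2)`, the prior df `d0` solves
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))`; when the right-hand
#' side is below `tol` the prior is effectively infinite and all variances
#' shrink to a common value. Then
#' `s0^2 = exp(mean(e) + digamma(d0/2) - ln(d0/2))` (`exp(mean(e))` for
#' infinite `d0`). Genes with zero pooled variance are excluded from the
#' fit but still receive moderated statistics downstream.
#'
#' @param summaries data.frame from [summarize_genes()].
#' @param min_genes minimum usable genes for a stable fit.
#' @param tol threshold below which `d0` is treated as infinite.
#' @return list of class `EBHyperparams` with `prior_df` and `prior_var`.
#' @export
estimate_hyperparams <- function(summaries, min_genes = 10L, tol = 1e-8) {
  ok <- is.finite(summaries$pooled_var) & summaries$pooled_var > 0
  if (sum(ok) < min_genes)
    stop("need at least ", min_genes, " genes with positive variance (got ",
         sum(ok), ")")
  d <- summaries$df[ok]
  e <- log(summaries$pooled_var[ok]) - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  rhs <- stats::var(e) - mean(trigamma(d / 2))
  if (!is.finite(rhs) || rhs < tol) {
    d0 <- Inf
    s0 <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(prior_df = d0, prior_var = s0), class = "EBHyperparams")
}

#' @export
print.EBHyperparams <- function(x, ...) {
  cat(sprintf("EBHyperparams: prior_df = %s, prior_var = %.6g\n",
              format(x$prior_df), x$prior_var))
  invisible(x)
}

#' Moderated t-statistics
#'
#' Shrinks each gene's variance to
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and forms
#' `t = mean_diff / (s_tilde * sqrt(v))`, referred to a t distribution with
#' `d0 + d_g` degrees of freedom (standard normal when `d0` is infinite).
#' Two-sided p-values.
#'
#' @param summaries data.frame from [summarize_genes()].
#' @param hyper list with `prior_df` (`>= 0`, may be `Inf`) and `prior_var`.
#' @return data.frame with `gene`, `t`, `df_total`, `p_value`.
#' @export
moderated_t <- function(summaries, hyper) {
  d0 <- hyper$prior_df; s0 <- hyper$prior_var
  if (!is.numeric(d0) || d0 < 0) stop("prior_df must be >= 0")
  if (is.infinite(d0)) {
    s2post <- rep(s0, nrow(summaries))
    df_tot <- rep(Inf, nrow(summaries))
  } else {
    s2post <- (d0 * s0 + summaries$df * summaries$pooled_var) / (d0 + summaries$df)
    df_tot <- d0 + summaries$df
  }
  tt <- summaries$mean_diff / sqrt(s2post * summaries$v)
  tt[summaries$mean_diff == 0] <- 0
  p <- ifelse(is.infinite(df_tot),
              2 * stats::pnorm(-abs(tt)),
              2 * stats::pt(-abs(tt), df_tot))
  # keep p strictly positive so log-based scores and BH stay defined
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  data.frame(gene = summaries$gene, t = tt, df_total = df_tot, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `adj_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and
#' returned in input order. Inputs must lie in `(0, 1]`.
#'
#' @param p_values numeric vector of raw p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Full per-study differential-expression analysis
#'
#' Summaries, hyperparameter estimation (unless supplied), moderated t,
#' BH adjustment and ranking. Ranks order by raw p-value with ties broken
#' lexicographically by gene symbol, so top-k lists are deterministic.
#'
#' @param dataset an [expression_dataset()].
#' @param hyper optional pre-estimated `EBHyperparams`.
#' @return data.frame of class `DEResult` with columns `gene`, `t`,
#'   `df_total`, `p_value`, `p_adjusted`, `rank`; the study id, disease and
#'   fitted hyperparameters are attached as attributes.
#' @export
run_de <- function(dataset, hyper = NULL) {
  sm <- summarize_genes(dataset)
  if (is.null(hyper)) hyper <- estimate_hyperparams(sm)
  mt <- moderated_t(sm, hyper)
  padj <- bh_adjust(mt$p_value)
  rk <- integer(nrow(mt))
  rk[order(mt$p_value, mt$gene)] <- seq_len(nrow(mt))
  res <- data.frame(gene = mt$gene, t = mt$t, df_total = mt$df_total,
                    p_value = mt$p_value, p_adjusted = padj, rank = rk,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "study_id") <- dataset$study_id
  attr(res, "disease") <- dataset$disease
  attr(res, "hyperparams") <- hyper
  class(res) <- c("DEResult", "data.frame")
  res
}
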
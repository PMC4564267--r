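# Gene-level meta-analysis across studies. Fisher's method
# (X = -2 sum ln p, chi-square with 2k df) flags genes driven by one or
# more very small study p-values; the maximum-p method (max p referred to
# its Beta(k, 1) null, i.e. meta_p = (max p)^k) demands consistently small
# p-values in every study.

#' Clamp p-values away from zero
#'
#' `max(p, floor)`, capped at 1. Applied before any log so that combined
#' statistics and signed log-p scores stay finite.
#'
#' @param p numeric vector of p-values (`>= 0`).
#' @param floor lower clamp.
#' @return clamped values.
#' @export
clamp_p <- function(p, floor = 1e-20) {
  if (any(!is.finite(p)) || any(p < 0)) stop("p-values must be finite and >= 0")
  pmin(pmax(p, floor), 1)
}

#' Fisher's p-value combination
#'
#' @param p_per_study clamped p-values of one gene, one per study.
#' @return `list(stat, p)`: `stat = -2 sum ln p_i`, `p` the upper tail of
#'   the chi-square distribution with `2k` df.
#' @export
fisher_combine <- function(p_per_study) {
  k <- length(p_per_study)
  if (k == 0L) stop("no p-values to combine")
  x <- -2 * sum(log(p_per_study))
  list(stat = x, p = stats::pchisq(x, df = 2 * k, lower.tail = FALSE))
}

#' Maximum-p combination
#'
#' @param p_per_study clamped p-values of one gene, one per study.
#' @return `list(stat, p)`: `stat = max p_i`, `p = stat^k` (the Beta(k, 1)
#'   upper-order-statistic null).
#' @export
maxp_combine <- function(p_per_study) {
  k <- length(p_per_study)
  if (k == 0L) stop("no p-values to combine")
  s <- max(p_per_study)
  list(stat = s, p = s^k)
}

#' Meta-analysis over all studies
#'
#' Combines the raw (not BH-adjusted) per-study moderated-t p-values of
#' every gene, clamped at `p_floor`, by the requested methods, then applies
#' BH adjustment across genes separately per method. All studies must share
#' the canonical filtered gene list.
#'
#' @param de_list list of `DEResult`s on one gene universe.
#' @param methods subset of `c("fisher", "maxp")`.
#' @param p_floor clamp floor passed to [clamp_p()].
#' @return data.frame of class `MetaResult` with `gene`, `k` and, per
#'   method, `<m>_stat`, `<m>_p`, `<m>_p_adj`.
#' @export
run_meta <- function(de_list, methods = c("fisher", "maxp"), p_floor = 1e-20) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(de_list)) stop("no studies to combine")
  genes <- de_list[[1L]]$gene
  for (de in de_list)
    if (!identical(de$gene, genes))
      stop("gene universe mismatch across studies")
  P <- vapply(de_list, function(d) clamp_p(d$p_value, p_floor),
              numeric(length(genes)))
  P <- matrix(P, nrow = length(genes))
  k <- ncol(P)
  out <- data.frame(gene = genes, k = k, row.names = NULL,
                    stringsAsFactors = FALSE)
  if ("fisher" %in% methods) {
    x <- -2 * rowSums(log(P))
    out$fisher_stat <- x
    out$fisher_p <- pmax(stats::pchisq(x, df = 2 * k, lower.tail = FALSE),
                         .Machine$double.xmin)
    out$fisher_p_adj <- bh_adjust(out$fisher_p)
  }
  if ("maxp" %in% methods) {
    s <- apply(P, 1L, max)
    out$maxp_stat <- s
    out$maxp_p <- s^k
    out$maxp_p_adj <- bh_adjust(out$maxp_p)
  }
  class(out) <- c("MetaResult", "data.frame")
  out
}
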
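# Independent brute-force oracles, deliberately written without reusing
# any package internals.

# BH step-up straight from the definition: adj_(i) = min_{j>=i} m p_(j)/j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Kendall tau-b by pair enumeration with tie correction.
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Hypergeometric upper tail by exact enumeration of combination counts.
hyper_oracle <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# Ordinary two-sample pooled-variance t-test per gene via stats::t.test.
pooled_t_oracle <- function(dataset) {
  is_case <- dataset$group == "case"
  t(apply(dataset$values, 1, function(x) {
    tt <- stats::t.test(x[is_case], x[!is_case], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  }))
}
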
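# Independent brute-force oracles (kept free of the implementation paths they
# check).

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n1+n2, n1) group assignments of the pooled values.
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p.value = min(p, 1))
}

# ssGSEA enrichment score by an explicit per-position running sum, using
# midrank^alpha weights on the descending-expression ordering.
ssgsea_oracle <- function(values, genes, set, alpha) {
  rk <- rank(values, ties.method = "average")
  ord <- order(values, decreasing = TRUE)
  g <- genes[ord]; w <- rk[ord]^alpha
  n <- length(genes); n_in <- sum(genes %in% set); n_out <- n - n_in
  cum_in <- 0; cum_out <- 0; es <- 0
  w_in_total <- sum(w[g %in% set])
  for (i in seq_len(n)) {
    if (g[i] %in% set) cum_in <- cum_in + w[i] else cum_out <- cum_out + 1
    p_in <- cum_in / w_in_total
    p_out <- if (n_out > 0) cum_out / n_out else 0
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# per-sample constrained least-squares flux minimizer for graphs where
# t(S) S + lambda * 1 1' is nonsingular (e.g. chains)
cls_oracle <- function(graph, ta, lambda = 1) {
  S <- incidence_matrix(graph)
  M <- ncol(S)
  A <- t(S) %*% S + lambda * matrix(1, M, M)
  t(vapply(ta, function(t1) drop(solve(A, lambda * t1 * rep(1, M))),
           numeric(M)))
}
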
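# Brute-force reference implementations used as independent oracles.
# All operate on plain binary adjacency matrices and use only elementary
# matrix operations, so they share no code path with the package.

# Shortest-path distances via matrix powers: d(i,j) is the smallest L with
# (A^L)[i,j] > 0.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  pw <- diag(n)
  for (L in seq_len(n - 1)) {
    pw <- pw %*% adj
    newly <- pw > 0 & !is.finite(d)
    d[newly] <- L
  }
  diag(d) <- 0
  d
}

# Number of shortest paths between each pair: minimal-length walks cannot
# revisit a vertex, so (A^d)[i,j] counts them exactly.
oracle_path_counts <- function(adj, d = oracle_distances(adj)) {
  n <- nrow(adj)
  powers <- vector("list", n)
  powers[[1]] <- adj
  for (L in 2:max(2, n - 1)) powers[[L]] <- powers[[L - 1]] %*% adj
  cnt <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) cnt[i, j] <- powers[[d[i, j]]][i, j]
  }
  cnt
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  tri <- diag(adj %*% adj %*% adj) / 2
  deg <- rowSums(adj)
  percol <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
  list(per_node = percol, cp = mean(percol))
}

oracle_char_path_length <- function(adj) {
  d <- oracle_distances(adj)
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

oracle_global_eff <- function(adj) {
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(adj)
  sum(inv) / (n * (n - 1))
}

oracle_nodal_eff <- function(adj) {
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (nrow(adj) - 1)
}

oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  per_node <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_eff(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  list(per_node = per_node, e_loc = mean(per_node))
}

# Betweenness from explicit shortest-path counts: for each pair (s,t) and
# interior node v, sigma_st(v)/sigma_st with
# sigma_st(v) = sigma_sv * sigma_vt when d(s,v) + d(v,t) = d(s,t).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  cnt <- oracle_path_counts(adj, d)
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        btw[v] <- btw[v] + cnt[s, v] * cnt[v, t] / cnt[s, t]
      }
    }
  }
  btw
}

# Random simple graph helpers for parameterised cases.
random_adjacency <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  ut <- which(upper.tri(adj))
  on <- ut[stats::runif(length(ut)) < p_edge]
  adj[on] <- 1L
  adj + t(adj)
}

adjacency_from_bits <- function(bits, n) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- bits
  adj + t(adj)
}

random_fc_matrix <- function(n) {
  m <- matrix(stats::rnorm(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
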
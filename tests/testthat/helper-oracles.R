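# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# enumerate every N-subset of 1..U, overlap it with the fixed M-subset
# 1..M, and count how often the overlap reaches n.
enum_hyper_tail <- function(n, M, N, U) {
  subs <- combn(U, N)
  overlaps <- colSums(subs <= M)
  mean(overlaps >= n)
}

# All upper-tail probabilities P(X >= n), n = 0..min(M,N), by enumeration.
enum_hyper_tail_all <- function(M, N, U) {
  subs <- combn(U, N)
  overlaps <- colSums(subs <= M)
  vapply(0:min(M, N), function(n) mean(overlaps >= n), 0)
}

# Brute-force MCODE vertex weight: iterative-deletion k-core search on an
# adjacency matrix, density over the closed neighborhood, zero below a
# 2-core or the degree cutoff.
brute_vertex_weight <- function(adj, v, degree_cutoff = 2) {
  deg <- rowSums(adj)
  if (deg[v] < degree_cutoff) return(0)
  nb <- which(adj[v, ] > 0)
  keep <- sort(c(v, nb))
  sub <- adj[keep, keep, drop = FALSE]
  n <- nrow(sub)
  kmax <- 0
  for (k in 2:max(2, n)) {
    cur <- rep(TRUE, n)
    repeat {
      d <- rowSums(sub[cur, cur, drop = FALSE])
      drop_v <- which(cur)[d < k]
      if (length(drop_v) == 0) break
      cur[drop_v] <- FALSE
      if (!any(cur)) break
    }
    if (any(cur)) kmax <- k else break
  }
  if (kmax < 2) return(0)
  m <- sum(sub) / 2
  kmax * (2 * m / (n * (n - 1)))
}

# Mean-rank-then-Pearson Spearman oracle.
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small igraph builders for structural fixtures.
make_clique <- function(ids) {
  g <- igraph::make_full_graph(length(ids))
  igraph::V(g)$name <- ids
  g
}

two_cliques_bridge <- function() {
  a <- paste0("a", 1:6)
  b <- paste0("b", 1:6)
  g <- igraph::disjoint_union(make_clique(a), make_clique(b))
  igraph::add_edges(g, c("a1", "b1"))
}

tiny_cfg <- function(background_target_prob = 0, ...) {
  sim_config(n_mirnas = 20, n_genes = 24, n_lincrnas = 8, n_modules = 2,
             module_size = 5, lincs_per_module = 1, mirnas_per_module = 4,
             background_target_prob = background_target_prob, ...)
}
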
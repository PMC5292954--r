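# Brute-force oracles, independent of igraph: Floyd-Warshall distances,
# combinatorial shortest-path counting for betweenness, iterative pruning
# for the k-core. Intended for graphs of <= 25 nodes.

bf_topology <- function(adj) {
  n <- nrow(adj)
  A <- (adj > 0) * 1L
  diag(A) <- 0L
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A == 1L] <- 1
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ds <- d[s, ]
    for (lev in sort(unique(ds[is.finite(ds) & ds > 0]))) {
      for (t in which(ds == lev)) {
        preds <- which(A[, t] == 1L & ds == lev - 1)
        sigma[s, t] <- sum(sigma[s, preds])
      }
    }
  }
  # pair-counting definition: credit v with sigma(s,v)*sigma(v,t)/sigma(s,t)
  # over all unordered pairs s < t whose shortest paths pass through v
  btw <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- outer(d[, v], d[v, ], "+") == d & is.finite(d) & upper.tri(d)
    on_path[v, ] <- FALSE
    on_path[, v] <- FALSE
    credit <- outer(sigma[, v], sigma[v, ]) / sigma
    btw[v] <- sum(credit[on_path])
  }
  clo <- vapply(seq_len(n), function(i) {
    same <- is.finite(d[i, ])
    nc <- sum(same)
    if (nc < 2L || n < 2L) return(0)
    ((nc - 1) / sum(d[i, same])) * ((nc - 1) / (n - 1))
  }, 0)
  core <- integer(n)
  for (k in seq_len(n)) {
    alive <- rep(1, n)
    repeat {
      deg <- as.vector(A %*% alive)
      drop <- alive == 1 & deg < k
      if (!any(drop)) break
      alive[drop] <- 0
    }
    core[alive == 1] <- k
  }
  list(degree = rowSums(A), betweenness = btw, closeness = clo, kcoreness = core)
}

random_test_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  rownames(adj) <- colnames(adj) <- sprintf("N%02d", seq_len(n))
  adj
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# small five-group expression fixture with known per-gene group means
fixture_expression <- function(means, noise = 0, n_per_group = 3, seed = 1) {
  set.seed(seed)
  groups <- rep(c("Con", "Mod", "DJ_alone", "DJGC_synergy", "DJGC_antagonism"),
                each = n_per_group)
  samples <- paste(groups, rep(seq_len(n_per_group), 5), sep = "_")
  expr <- means[, groups, drop = FALSE] +
    matrix(stats::rnorm(nrow(means) * length(samples), 0, noise), nrow(means))
  dimnames(expr) <- list(rownames(means), samples)
  list(expr = expr, groups = stats::setNames(groups, samples))
}
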
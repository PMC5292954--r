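#' Markov clustering (MCL) of an interaction network
#'
#' Canonical MCL on the (optionally weighted) adjacency matrix: self-loops
#' are added with weight equal to the node's maximum incident edge weight,
#' columns are normalized to a stochastic flow matrix, and expansion
#' (matrix power) alternates with inflation (elementwise power followed by
#' column renormalization) and pruning of small entries until the flow
#' matrix stops changing. Clusters are read off the attractor structure of
#' the limit matrix: attractor rows with overlapping attractor support are
#' merged into one attractor system, and every node is assigned to the
#' system holding most of its flow mass (ties broken towards the module
#' containing the lexicographically smallest gene).
#'
#' Disconnected components can never exchange flow, so they always end in
#' distinct modules, and the partition depends on the graph only up to node
#' relabeling.
#'
#' @param network an `igraph` network. Edge attribute `combined_score` is
#'   used as the flow weight when present and `use_weights = TRUE`.
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param prune_threshold entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence tolerance on the max absolute change (default 1e-8).
#' @param use_weights logical; use `combined_score` edge weights.
#' @return object of class `module_partition`: list with `membership`
#'   (named integer vector, module ids 1..k), `modules` (list of gene
#'   vectors ordered by decreasing size), `converged`, `iterations` and
#'   `params`.
#' @export
mcl_cluster <- function(network, inflation = 2.0, expansion = 2,
                        prune_threshold = 1e-5, max_iter = 200,
                        tol = 1e-8, use_weights = TRUE) {
  n <- igraph::vcount(network)
  if (n == 0L) stop("empty network")
  genes <- igraph::V(network)$name
  if (is.null(genes)) genes <- as.character(seq_len(n))
  w <- NULL
  if (use_weights && "combined_score" %in% igraph::edge_attr_names(network)) {
    w <- igraph::E(network)$combined_score
  }
  A <- as.matrix(igraph::as_adjacency_matrix(network, attr = if (is.null(w)) NULL else "combined_score",
                                             sparse = FALSE))
  A[A < 0] <- 0
  diag(A) <- apply(A, 1L, max)          # self-loop = max incident weight
  diag(A)[diag(A) == 0] <- 1            # isolated node keeps its own flow
  normalize <- function(M) sweep(M, 2L, colSums(M), "/")
  M <- normalize(A)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune_threshold] <- 0
    cs <- colSums(Minf)
    dead <- cs == 0                     # fully pruned column: restore self-flow
    if (any(dead)) {
      Minf[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Mnew <- sweep(Minf, 2L, cs, "/")
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge in ", max_iter,
                          " iterations; returning partial result")
  eps <- prune_threshold
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- seq_len(n)
  # union attractor rows whose supports share an attractor (periodic systems)
  parent <- seq_along(attractors)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  support <- lapply(attractors, function(i) which(M[i, ] > eps))
  for (i in seq_along(attractors)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(intersect(support[[i]], attractors),
                           intersect(support[[j]], attractors)))) {
        parent[find(i)] <- find(j)
      }
    }
  }
  sys_id <- vapply(seq_along(attractors), find, 0L)
  systems <- split(seq_along(attractors), sys_id)
  # assign every node to the attractor system with the largest flow mass
  mass <- matrix(0, length(systems), n)
  for (s in seq_along(systems)) {
    rows <- attractors[systems[[s]]]
    mass[s, ] <- colSums(M[rows, , drop = FALSE])
  }
  membership <- integer(n)
  for (v in seq_len(n)) {
    best <- which(mass[, v] == max(mass[, v]))
    if (max(mass[, v]) == 0) {          # no attractor claims it: own module
      membership[v] <- NA_integer_
    } else if (length(best) == 1L) {
      membership[v] <- best
    } else {
      # tie: module whose smallest member gene sorts first
      anchor <- vapply(best, function(s) {
        rows <- attractors[systems[[s]]]
        min(genes[rows])
      }, "")
      membership[v] <- best[order(anchor)][1L]
    }
  }
  if (anyNA(membership)) {
    extra <- max(membership, na.rm = TRUE)
    for (v in which(is.na(membership))) {
      extra <- extra + 1L
      membership[v] <- extra
    }
  }
  # deterministic module ids: decreasing size, then smallest gene
  tabs <- split(seq_len(n), membership)
  ord <- order(-lengths(tabs),
               vapply(tabs, function(ix) min(genes[ix]), ""))
  relabel <- integer(length(tabs))
  relabel[ord] <- seq_along(tabs)
  membership <- relabel[match(membership, names(tabs))]
  names(membership) <- genes
  modules <- lapply(seq_len(max(membership)), function(m) sort(genes[membership == m]))
  structure(list(membership = membership, modules = modules,
                 converged = converged, iterations = iter,
                 params = list(inflation = inflation, expansion = expansion,
                               prune_threshold = prune_threshold,
                               max_iter = max_iter, tol = tol,
                               use_weights = use_weights)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("MCL partition: %d module(s) over %d node(s) (inflation %g%s)\n",
              length(x$modules), length(x$membership), x$params$inflation,
              if (x$converged) sprintf(", converged in %d iterations", x$iterations)
              else ", NOT converged"))
  sizes <- lengths(x$modules)
  cat("  module sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
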
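#' Build the three-class gene interaction network
#'
#' Candidate edges are interactions whose endpoints both belong to the union
#' of the role sets. The construction threshold is the median combined score
#' over candidate edges; edges with score >= threshold (boundary kept) are
#' retained and isolated nodes dropped. Vertices carry logical role flags
#' (`ascites_related`, `combination_related`, `known_target`), the union of
#' their memberships.
#'
#' @param genes_by_role named list with elements `ascites_related`,
#'   `combination_related`, `known_target` (character vectors; at least one
#'   non-empty).
#' @param interactions interaction data frame from
#'   [read_interaction_table()] (columns node_a, node_b, combined_score).
#' @param score_threshold optional fixed threshold overriding the median
#'   rule.
#' @return undirected `igraph` with edge attribute `combined_score`, vertex
#'   role flags, and graph attribute `score_threshold`.
#' @export
build_network <- function(genes_by_role, interactions, score_threshold = NULL) {
  roles <- c("ascites_related", "combination_related", "known_target")
  genes_by_role <- lapply(stats::setNames(roles, roles), function(r) {
    g <- genes_by_role[[r]]
    if (is.null(g)) character() else unique(canonicalize_symbols(g))
  })
  universe <- unique(unlist(genes_by_role, use.names = FALSE))
  if (!length(universe)) stop("all role sets are empty")
  cand <- interactions[interactions$node_a %in% universe &
                       interactions$node_b %in% universe, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no candidate interactions among role genes")
  thr <- if (is.null(score_threshold)) stats::median(cand$combined_score) else score_threshold
  keep <- cand[cand$combined_score >= thr, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = keep$node_a, to = keep$node_b,
               combined_score = keep$combined_score),
    directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(combined_score = "max"))
  for (r in roles) {
    g <- igraph::set_vertex_attr(g, r, value = igraph::V(g)$name %in% genes_by_role[[r]])
  }
  igraph::graph_attr(g, "score_threshold") <- thr
  g
}

#' Compute the four topological features of every node
#'
#' Degree (incident edge count), betweenness (exact Brandes algorithm,
#' unnormalized, with fractional credit over tied shortest paths, unweighted
#' paths), closeness with Wasserman-Faust component scaling, and k-coreness
#' (largest k whose k-core contains the node). Closeness of a node in a
#' component of size `nc` within a graph of `n` nodes is
#' `((nc-1)/sum(d)) * ((nc-1)/(n-1))` where the sum runs over within-component
#' distances; isolated vertices get 0 and a singleton graph gets 0.
#'
#' @param network an `igraph` network.
#' @return data frame with columns gene, degree, betweenness, closeness,
#'   kcoreness, in vertex order.
#' @export
compute_topology <- function(network) {
  n <- igraph::vcount(network)
  if (n == 0L) stop("empty network")
  deg <- igraph::degree(network)
  btw <- igraph::betweenness(network, directed = FALSE, weights = NA,
                             normalized = FALSE)
  d <- igraph::distances(network, weights = NA)
  comp <- igraph::components(network)$membership
  clo <- vapply(seq_len(n), function(i) {
    same <- comp == comp[i]
    nc <- sum(same)
    if (nc < 2L || n < 2L) return(0)
    ((nc - 1) / sum(d[i, same])) * ((nc - 1) / (n - 1))
  }, 0)
  data.frame(gene = igraph::V(network)$name,
             degree = as.numeric(deg),
             betweenness = as.numeric(btw),
             closeness = clo,
             kcoreness = as.numeric(igraph::coreness(network)),
             stringsAsFactors = FALSE)
}

#' Select hub genes
#'
#' Hubs are nodes whose degree is strictly greater than twice the median
#' degree over all nodes of the network.
#'
#' @param topology topology data frame from [compute_topology()].
#' @param multiplier degree-median multiplier (default 2).
#' @return character vector of hub genes with attributes `median_degree`
#'   and `threshold`.
#' @export
select_hubs <- function(topology, multiplier = 2) {
  med <- stats::median(topology$degree)
  hubs <- sort(topology$gene[topology$degree > multiplier * med])
  structure(hubs, median_degree = med, threshold = multiplier * med)
}

#' Induced subnetwork on the hub genes
#'
#' Keeps only direct interactions among hubs; hubs isolated within the
#' subnetwork are dropped.
#'
#' @param network the full `igraph` network.
#' @param hubs character vector of hub genes (subset of the network nodes).
#' @return an `igraph` subnetwork.
#' @export
hub_subnetwork <- function(network, hubs) {
  if (!length(hubs)) stop("empty hub set")
  stopifnot(all(hubs %in% igraph::V(network)$name))
  sub <- igraph::induced_subgraph(network, hubs)
  igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
}

#' Select major hubs
#'
#' Major hubs are hubs whose degree, betweenness, closeness and k-coreness
#' are each strictly greater than that feature's median over all nodes of
#' the topology table supplied (by default the full network's, see the
#' methods vignette for the rationale).
#'
#' @param topology topology data frame (typically of the full network).
#' @param hubs character vector of hubs.
#' @return character vector of major hub genes with attribute `medians`.
#' @export
select_major_hubs <- function(topology, hubs) {
  feats <- c("degree", "betweenness", "closeness", "kcoreness")
  med <- vapply(feats, function(f) stats::median(topology[[f]]), 0)
  idx <- topology$gene %in% hubs
  pass <- idx
  for (f in feats) pass <- pass & topology[[f]] > med[[f]]
  structure(sort(topology$gene[pass]), medians = med)
}

#' Extract the seed-anchored signal axis
#'
#' Builds the seed sub-network: the induced subgraph on the two seeds plus
#' the major hubs (whose edges are, by construction, those incident to a
#' seed or between major hubs), then takes the shortest path from
#' `seed_a` to `seed_b`. Ties among equally short paths are broken by the
#' higher minimum edge combined score, then by the lexicographically
#' smallest gene sequence. The path is annotated with every pathway
#' containing at least `annotate_fraction` of its genes.
#'
#' @param network the full `igraph` network with role flags.
#' @param major_hubs character vector of major hub genes.
#' @param seed_a combination-related seed gene.
#' @param seed_b known-therapeutic-target seed gene.
#' @param pathways optional `gene_set_collection` for annotation.
#' @param annotate_fraction minimum fraction of axis genes a pathway must
#'   contain to annotate the axis (default 0.8).
#' @return object of class `axis_path`: list with `found`, `genes` (ordered,
#'   NULL when not found), `edges` (data frame from, to, combined_score),
#'   `pathways` (annotating set ids) and `reason` when not found.
#' @export
extract_axis <- function(network, major_hubs, seed_a, seed_b,
                         pathways = NULL, annotate_fraction = 0.8) {
  vn <- igraph::V(network)$name
  seed_a <- canonicalize_symbols(seed_a)
  seed_b <- canonicalize_symbols(seed_b)
  if (!seed_a %in% vn) stop("seed_a not in network: ", seed_a)
  if (!seed_b %in% vn) stop("seed_b not in network: ", seed_b)
  if (!isTRUE(igraph::vertex_attr(network, "combination_related")[match(seed_a, vn)]))
    stop("seed_a lacks the combination_related role: ", seed_a)
  if (!isTRUE(igraph::vertex_attr(network, "known_target")[match(seed_b, vn)]))
    stop("seed_b lacks the known_target role: ", seed_b)
  members <- union(c(seed_a, seed_b), intersect(major_hubs, vn))
  sub <- igraph::induced_subgraph(network, members)
  no_axis <- function(reason) {
    structure(list(found = FALSE, genes = NULL, edges = NULL,
                   pathways = character(), reason = reason,
                   seed_a = seed_a, seed_b = seed_b),
              class = "axis_path")
  }
  dist_ab <- igraph::distances(sub, v = seed_a, to = seed_b, weights = NA)[1, 1]
  if (!is.finite(dist_ab)) return(no_axis("seeds disconnected in the seed sub-network"))
  paths <- igraph::all_shortest_paths(sub, from = seed_a, to = seed_b,
                                      weights = NA)$vpaths
  path_genes <- lapply(paths, function(p) igraph::V(sub)$name[as.integer(p)])
  min_score <- vapply(path_genes, function(g) {
    eids <- igraph::get_edge_ids(sub, rbind(g[-length(g)], g[-1]))
    min(igraph::E(sub)$combined_score[eids])
  }, 0)
  best <- which(min_score == max(min_score))
  if (length(best) > 1L) {
    keys <- vapply(path_genes[best], paste, "", collapse = "\r")
    best <- best[order(keys)][1L]
  }
  genes <- path_genes[[best]]
  eids <- igraph::get_edge_ids(sub, rbind(genes[-length(genes)], genes[-1]))
  edges <- data.frame(from = genes[-length(genes)], to = genes[-1],
                      combined_score = igraph::E(sub)$combined_score[eids],
                      stringsAsFactors = FALSE)
  annot <- character()
  if (!is.null(pathways)) {
    frac <- vapply(pathways, function(s) mean(genes %in% s), 0)
    annot <- names(pathways)[frac >= annotate_fraction]
  }
  structure(list(found = TRUE, genes = genes, edges = edges,
                 pathways = annot, seed_a = seed_a, seed_b = seed_b),
            class = "axis_path")
}

#' @export
print.axis_path <- function(x, ...) {
  if (!x$found) {
    cat("No axis:", x$reason, "\n")
    return(invisible(x))
  }
  cat("Signal axis:", paste(x$genes, collapse = "-"), "\n")
  if (length(x$pathways)) cat("  annotated pathways:", paste(x$pathways, collapse = ", "), "\n")
  invisible(x)
}
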
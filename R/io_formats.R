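#' Canonicalize gene symbols
#'
#' Collapses the mixed symbol casing found across expression platforms,
#' interaction databases and pathway files onto the capitalized mouse-style
#' convention (`"FRK"`, `"frk"` -> `"Frk"`). Applied at every reader boundary
#' so that identifiers join across sources.
#'
#' @param x character vector of gene symbols.
#' @return character vector of the same length, trimmed and case-folded.
#' @export
#' @examples
#' canonicalize_symbols(c("FRK", "avpr2", " Aqp4 "))
canonicalize_symbols <- function(x) {
  x <- trimws(as.character(x))
  out <- tolower(x)
  substr(out, 1L, 1L) <- toupper(substr(out, 1L, 1L))
  out[x == ""] <- ""
  out
}

#' Read a log2 expression table and its sample-group map
#'
#' The expression file is a TSV with a header row of sample identifiers and
#' gene/probe identifiers in the first column; values are log2-scale
#' expression. The group map is a two-column TSV (`sample_id<TAB>group`)
#' without a header. Missing cells may be encoded `NA` and are retained.
#'
#' @param path path to the expression TSV.
#' @param group_map_path path to the sample-to-group TSV.
#' @param id_level `"gene"` or `"probe"`; with `"gene"` the row identifiers
#'   are canonicalized and must be unique.
#' @return list with elements `expr` (numeric matrix, genes x samples),
#'   `groups` (named character vector, names = sample ids) and `id_level`.
#' @export
read_expression_table <- function(path, group_map_path, id_level = c("gene", "probe")) {
  id_level <- match.arg(id_level)
  if (!file.size(path) > 0) stop("empty expression file: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(tab) == 0L || ncol(tab) < 2L) stop("expression table needs >=1 gene row and >=1 sample column")
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in expression header: ",
                                      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  ids <- as.character(tab[[1L]])
  if (id_level == "gene") {
    ids <- canonicalize_symbols(ids)
    if (anyDuplicated(ids)) stop("duplicate gene ids after canonicalization: ",
                                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  } else if (anyDuplicated(ids)) {
    stop("duplicate probe ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(num <- apply(tab[, -1L, drop = FALSE], 2L, as.numeric))
    bad <- is.na(num) & !is.na(as.matrix(tab[, -1L, drop = FALSE]))
    if (any(bad)) stop("non-numeric expression cells, e.g. row ",
                       which(rowSums(bad) > 0)[1L])
    vals <- matrix(num, nrow = nrow(tab), dimnames = list(NULL, sample_ids))
  }
  rownames(vals) <- ids
  groups <- read_group_map(group_map_path)
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing)) stop("samples missing from group map: ", paste(missing, collapse = ", "))
  groups <- groups[sample_ids]
  list(expr = vals, groups = groups, id_level = id_level)
}

read_group_map <- function(path) {
  gm <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(gm) < 2L) stop("group map must have two columns: sample_id<TAB>group")
  if (anyDuplicated(gm[[1L]])) stop("duplicate sample ids in group map")
  stats::setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
}

#' Read an interaction edge table
#'
#' Supports the STRING `protein.links` dialect (whitespace-separated with
#' header `protein1 protein2 combined_score`) and a headerless three-column
#' TSV. Identifiers are canonicalized; an optional two-column mapping table
#' (`from<TAB>to`, e.g. taxon-prefixed protein id to gene symbol) is applied
#' first. Self-pairs are dropped with a warning and duplicate pairs collapse
#' to their maximum combined score.
#'
#' @param path path to the edge file.
#' @param dialect `"string_links"` or `"tsv3col"`.
#' @param id_map optional data frame (columns `from`, `to`) or path to a
#'   two-column TSV mapping raw identifiers to gene symbols; unmapped
#'   identifiers are kept as-is after canonicalization.
#' @return data frame with columns `node_a`, `node_b`, `combined_score`,
#'   canonicalized so that `node_a < node_b` lexicographically.
#' @export
read_interaction_table <- function(path, dialect = c("string_links", "tsv3col"),
                                   id_map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "string_links") {
    raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    if (nrow(raw) > 0 && ncol(raw) < 3L) stop("string_links needs 3 columns")
    if (nrow(raw) == 0L) {
      warning("empty interaction file: ", path)
      return(data.frame(node_a = character(), node_b = character(),
                        combined_score = numeric(), stringsAsFactors = FALSE))
    }
    raw <- raw[, 1:3]
  } else {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(raw) == 0L) {
      warning("empty interaction file: ", path)
      return(data.frame(node_a = character(), node_b = character(),
                        combined_score = numeric(), stringsAsFactors = FALSE))
    }
    if (ncol(raw) < 3L) stop("tsv3col needs 3 columns")
    raw <- raw[, 1:3]
  }
  names(raw) <- c("node_a", "node_b", "combined_score")
  suppressWarnings(raw$combined_score <- as.numeric(raw$combined_score))
  if (anyNA(raw$combined_score)) stop("malformed combined_score in row ",
                                      which(is.na(raw$combined_score))[1L])
  if (any(raw$combined_score < 0)) stop("negative combined_score in row ",
                                        which(raw$combined_score < 0)[1L])
  if (!is.null(id_map)) {
    if (is.character(id_map)) id_map <- utils::read.delim(id_map, header = FALSE,
                                                          stringsAsFactors = FALSE)
    map <- stats::setNames(as.character(id_map[[2L]]), as.character(id_map[[1L]]))
    remap <- function(v) ifelse(v %in% names(map), unname(map[v]), v)
    raw$node_a <- remap(as.character(raw$node_a))
    raw$node_b <- remap(as.character(raw$node_b))
  }
  canonicalize_interactions(raw)
}

#' @keywords internal
canonicalize_interactions <- function(tab) {
  a <- canonicalize_symbols(tab$node_a)
  b <- canonicalize_symbols(tab$node_b)
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    a <- a[!self]; b <- b[!self]
    tab <- tab[!self, , drop = FALSE]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- data.frame(node_a = lo, node_b = hi,
                    combined_score = tab$combined_score, stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(out)
  key <- paste(out$node_a, out$node_b, sep = "\r")
  score <- tapply(out$combined_score, key, max)
  keys <- sort(names(score))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(parts, `[`, "", 1L),
                    node_b = vapply(parts, `[`, "", 2L),
                    combined_score = as.numeric(score[keys]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `set_id<TAB>description<TAB>gene...`.
#' Members are canonicalized and de-duplicated per set.
#'
#' @param path path to a GMT file.
#' @return object of class `gene_set_collection`: a named list of character
#'   vectors with a `descriptions` attribute (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields")
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set_id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(canonicalize_symbols(f[-(1:2)])))
  names(sets) <- ids
  gene_set_collection(sets, vapply(fields, `[`, "", 2L))
}

#' @keywords internal
gene_set_collection <- function(sets, descriptions = rep("", length(sets))) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param sets a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain gene list
#'
#' One gene per line; an optional second tab-separated column carries a
#' free-text annotation and is ignored for membership. Symbols are
#' canonicalized and de-duplicated, preserving first-occurrence order.
#'
#' @param path path to the list file.
#' @return character vector of unique canonical symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  genes <- canonicalize_symbols(vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L))
  unique(genes)
}

#' Write node and edge tables for a gene network
#'
#' Writes `<out_prefix>_nodes.tsv` (gene, roles, degree, betweenness,
#' closeness, kcore, is_hub, is_major_hub, module) and `<out_prefix>_edges.tsv`
#' (a, b, combined_score). Topology/hub/module columns are written as `NA`
#' when the corresponding vertex attribute is absent. Reading the pair back
#' with [read_network_tables()] reproduces the network exactly.
#'
#' @param network an annotated `igraph` network from [build_network()].
#' @param out_prefix path prefix for the two files.
#' @return named character vector with the two paths, invisibly.
#' @export
write_network_tables <- function(network, out_prefix) {
  if (igraph::vcount(network) == 0L) stop("cannot write an empty network")
  va <- igraph::vertex_attr_names(network)
  n <- igraph::vcount(network)
  get_attr <- function(name, default = rep(NA, n)) {
    if (name %in% va) igraph::vertex_attr(network, name) else default
  }
  roles <- vapply(seq_len(n), function(i) {
    fl <- c(ascites_related = isTRUE(get_attr("ascites_related")[i]),
            combination_related = isTRUE(get_attr("combination_related")[i]),
            known_target = isTRUE(get_attr("known_target")[i]))
    paste(names(fl)[fl], collapse = ",")
  }, "")
  nodes <- data.frame(
    gene = igraph::V(network)$name,
    roles = roles,
    degree = get_attr("degree"),
    betweenness = get_attr("betweenness"),
    closeness = get_attr("closeness"),
    kcore = get_attr("kcore"),
    is_hub = get_attr("is_hub"),
    is_major_hub = get_attr("is_major_hub"),
    module = get_attr("module"),
    stringsAsFactors = FALSE
  )
  el <- igraph::as_edgelist(network)
  edges <- data.frame(a = pmin(el[, 1L], el[, 2L]), b = pmax(el[, 1L], el[, 2L]),
                      combined_score = igraph::E(network)$combined_score,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  node_path <- paste0(out_prefix, "_nodes.tsv")
  edge_path <- paste0(out_prefix, "_edges.tsv")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nodes = node_path, edges = edge_path))
}

#' Read back a network written by [write_network_tables()]
#' @param out_prefix the prefix given to [write_network_tables()].
#' @return an `igraph` network with the same vertices, edges and attributes.
#' @export
read_network_tables <- function(out_prefix) {
  nodes <- utils::read.delim(paste0(out_prefix, "_nodes.tsv"), stringsAsFactors = FALSE)
  edges <- utils::read.delim(paste0(out_prefix, "_edges.tsv"), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$a, to = edges$b, combined_score = edges$combined_score),
    directed = FALSE,
    vertices = data.frame(name = nodes$gene, stringsAsFactors = FALSE))
  idx <- match(igraph::V(g)$name, nodes$gene)
  role_flags <- strsplit(ifelse(is.na(nodes$roles), "", nodes$roles), ",", fixed = TRUE)
  for (role in c("ascites_related", "combination_related", "known_target")) {
    g <- igraph::set_vertex_attr(g, role,
      value = vapply(role_flags[idx], function(f) role %in% f, TRUE))
  }
  for (col in c("degree", "betweenness", "closeness", "kcore", "is_hub",
                "is_major_hub", "module")) {
    if (!all(is.na(nodes[[col]]))) {
      g <- igraph::set_vertex_attr(g, col, value = nodes[[col]][idx])
    }
  }
  g
}

#' Write an expression matrix and group map as TSVs
#' @param expr numeric matrix, genes x samples.
#' @param groups named character vector mapping sample id to group.
#' @param expr_path,group_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression_table <- function(expr, groups, expr_path, group_path) {
  tab <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(names(groups), unname(groups)), group_path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(expr_path, group_path))
}

#' Write an interaction table in the headerless three-column TSV dialect
#' @param interactions data frame with `node_a`, `node_b`, `combined_score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
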
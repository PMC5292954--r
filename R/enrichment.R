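#' Hypergeometric over-representation analysis with Bonferroni correction
#'
#' For each pathway the raw p-value is the hypergeometric upper tail
#' P(X >= k) with population size N (the universe), K pathway genes in the
#' universe, n query genes and k overlap; equivalently a one-sided Fisher
#' test. The Bonferroni multiplier is the number of pathways with nonzero
#' universe overlap (those actually tested), and corrected p-values are
#' capped at 1.
#'
#' @param query character vector of query genes. Genes outside the universe
#'   are dropped with a warning.
#' @param pathways a `gene_set_collection`.
#' @param universe character vector of background genes.
#' @return data frame with columns set_id, N, K, n, k, raw_p, bonferroni_p,
#'   genes (comma-separated overlap), sorted by raw_p ascending with ties
#'   broken by set_id.
#' @export
enrich <- function(query, pathways, universe) {
  if (!length(query)) stop("empty query gene list")
  if (!length(pathways)) stop("empty pathway collection")
  query <- unique(canonicalize_symbols(query))
  universe <- unique(canonicalize_symbols(universe))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("no query genes remain within the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(pathways), function(id) {
    set_u <- intersect(pathways[[id]], universe)
    K <- length(set_u)
    if (K == 0L) return(NULL)
    overlap <- intersect(query, set_u)
    k <- length(overlap)
    raw_p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, N = N, K = K, n = n, k = k, raw_p = raw_p,
               genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(set_id = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), raw_p = numeric(),
                      bonferroni_p = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  n_tested <- nrow(out)
  out$bonferroni_p <- pmin(1, out$raw_p * n_tested)
  out <- out[order(out$raw_p, out$set_id),
             c("set_id", "N", "K", "n", "k", "raw_p", "bonferroni_p", "genes")]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}
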
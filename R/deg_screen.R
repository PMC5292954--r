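#' Screen differentially expressed genes between two groups
#'
#' Per-gene two-sample test on log2 expression with the screening rule
#' |log2FC| >= `fc_threshold` (inclusive) and p < `p_threshold` (strict).
#' log2FC is mean(test) - mean(reference). Missing values are handled
#' pairwise-complete; a gene is testable only when both groups retain at
#' least two non-missing samples.
#'
#' @param expr numeric matrix of log2 expression, genes x samples, with
#'   gene row names and sample column names.
#' @param groups named character vector mapping sample id to group label.
#' @param reference,test group labels; log2FC is test minus reference.
#' @param fc_threshold minimum absolute log2 fold change (default 1).
#' @param p_threshold strict p-value cutoff (default 0.05).
#' @param method `"student"` (pooled-variance t, the default), `"welch"`
#'   (Satterthwaite df) or `"limma"` (moderated t via the limma package).
#'   With only three samples per group the pooled t is exact under a
#'   homoscedastic Gaussian model, whereas the Welch approximation is
#'   noticeably conservative; see the methods vignette.
#' @return object of class `deg_result`: list with `table` (data frame of
#'   gene, log2fc, p_value, direction, passing, neg_log10_p), `passing`
#'   (character vector of passing genes), `reference`, `test`, thresholds
#'   and `method`.
#' @export
screen_degs <- function(expr, groups, reference, test,
                        fc_threshold = 1.0, p_threshold = 0.05,
                        method = c("student", "welch", "limma")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (identical(reference, test)) stop("reference and test groups must differ")
  for (g in c(reference, test)) {
    if (!g %in% groups) stop("unknown group label: ", g)
    if (sum(groups == g) < 2L) stop("group ", g, " has fewer than 2 samples")
  }
  samp <- colnames(expr)
  ia <- samp[samp %in% names(groups)[groups == reference]]
  ib <- samp[samp %in% names(groups)[groups == test]]
  if (length(ia) < 2L || length(ib) < 2L) stop("both groups need >=2 samples present in the matrix")
  xa <- expr[, ia, drop = FALSE]
  xb <- expr[, ib, drop = FALSE]
  st <- if (method == "limma") {
    moderated_stats(xa, xb)
  } else {
    two_sample_stats(xa, xb, pooled = (method == "student"))
  }
  tab <- data.frame(
    gene = rownames(expr),
    log2fc = st$fc,
    p_value = st$p,
    direction = ifelse(st$fc > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  tab$passing <- !is.na(tab$p_value) & abs(tab$log2fc) >= fc_threshold &
    tab$p_value < p_threshold
  tab$neg_log10_p <- -log10(tab$p_value)
  rownames(tab) <- NULL
  structure(list(table = tab, passing = tab$gene[tab$passing],
                 reference = reference, test = test,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 method = method),
            class = "deg_result")
}

# Vectorized two-sample t with pairwise-complete NA handling.
# fc = mean(b) - mean(a). Genes with <2 complete samples in a group get NA p.
two_sample_stats <- function(xa, xb, pooled = TRUE) {
  gstats <- function(x) {
    ok <- !is.na(x)
    n <- rowSums(ok)
    x0 <- ifelse(ok, x, 0)
    m <- rowSums(x0) / n
    v <- (rowSums(x0^2) - n * m^2) / pmax(n - 1L, 1L)
    v[n < 2L] <- NA_real_
    list(n = n, m = m, v = pmax(v, 0))
  }
  a <- gstats(xa); b <- gstats(xb)
  fc <- b$m - a$m
  if (pooled) {
    df <- a$n + b$n - 2L
    sp2 <- ((a$n - 1L) * a$v + (b$n - 1L) * b$v) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se2a <- a$v / a$n; se2b <- b$v / b$n
    se <- sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (a$n - 1L) + se2b^2 / (b$n - 1L))
  }
  t <- fc / se
  p <- 2 * stats::pt(-abs(t), df)
  p[a$n < 2L | b$n < 2L] <- NA_real_
  p[!is.na(se) & se == 0 & fc != 0] <- 0
  list(fc = fc, p = p)
}

moderated_stats <- function(xa, xb) {
  if (!requireNamespace("limma", quietly = TRUE)) {
    stop("method = 'limma' requires the limma package")
  }
  x <- cbind(xa, xb)
  design <- cbind(intercept = 1, test = rep(c(0, 1), c(ncol(xa), ncol(xb))))
  fit <- limma::eBayes(limma::lmFit(x, design))
  list(fc = fit$coefficients[, "test"], p = fit$p.value[, "test"])
}

#' @export
print.deg_result <- function(x, ...) {
  cat("DEG screen:", x$reference, "vs", x$test,
      sprintf("(|log2FC| >= %g, p < %g, %s t)\n",
              x$fc_threshold, x$p_threshold, x$method))
  up <- sum(x$table$passing & x$table$direction == "up")
  dn <- sum(x$table$passing & x$table$direction == "down")
  cat(sprintf("  %d genes tested, %d passing (%d up, %d down)\n",
              nrow(x$table), up + dn, up, dn))
  invisible(x)
}

#' Collapse probe-level rows to gene level
#'
#' @param expr numeric matrix with probe row names.
#' @param probe_map data frame whose first two columns map probe id to gene
#'   symbol (symbols are canonicalized).
#' @param rule `"max_mean_abs"` keeps the probe with the largest mean
#'   absolute log2 value across samples (default); `"max_var"` keeps the
#'   most variable probe; `"mean"` averages probes per gene.
#' @return numeric matrix with one row per gene. Unmapped probes are dropped
#'   with a message reporting the count.
#' @export
collapse_probes <- function(expr, probe_map, rule = c("max_mean_abs", "max_var", "mean")) {
  rule <- match.arg(rule)
  map <- stats::setNames(canonicalize_symbols(probe_map[[2L]]),
                         as.character(probe_map[[1L]]))
  map <- map[nzchar(map)]
  mapped <- rownames(expr) %in% names(map)
  if (!any(mapped)) stop("no probes in the expression table are covered by the map")
  if (any(!mapped)) message(sum(!mapped), " unmapped probe(s) dropped")
  x <- expr[mapped, , drop = FALSE]
  gene <- unname(map[rownames(x)])
  if (rule == "mean") {
    out <- rowsum(x, gene) / as.vector(table(gene)[sort(unique(gene))])
    return(out[order(rownames(out)), , drop = FALSE])
  }
  score <- switch(rule,
    max_mean_abs = rowMeans(abs(x), na.rm = TRUE),
    max_var = apply(x, 1L, stats::var, na.rm = TRUE))
  # deterministic: break score ties by probe id
  ord <- order(gene, -score, rownames(x))
  keep <- ord[!duplicated(gene[ord])]
  out <- x[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' Hierarchical clustering of DEGs and samples
#'
#' Agglomerative clustering with Euclidean distance and average linkage on
#' the DEG-restricted expression matrix, for genes (rows) and samples
#' (columns). Rows and columns are sorted lexicographically beforehand so
#' the merge order is deterministic under distance ties.
#'
#' @param expr numeric matrix restricted to DEGs (>= 2 rows).
#' @return object of class `deg_clustering`: list with `gene_hclust` and
#'   `sample_hclust` (both `hclust` objects).
#' @export
cluster_degs <- function(expr) {
  if (!is.matrix(expr) || nrow(expr) < 2L) stop("need >=2 DEG rows to cluster")
  expr <- expr[order(rownames(expr)), order(colnames(expr)), drop = FALSE]
  structure(list(
    gene_hclust = stats::hclust(stats::dist(expr, method = "euclidean"),
                                method = "average"),
    sample_hclust = stats::hclust(stats::dist(t(expr), method = "euclidean"),
                                  method = "average")),
    class = "deg_clustering")
}

#' @export
print.deg_clustering <- function(x, ...) {
  cat("DEG clustering (Euclidean, average linkage):",
      length(x$gene_hclust$labels), "genes x",
      length(x$sample_hclust$labels), "samples\n")
  invisible(x)
}
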
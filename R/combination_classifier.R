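#' Category rules for combination-related genes
#'
#' Six directional categories describe how a treatment relates to the
#' disease-model dysregulation: C1/C2 (and mirrored C4/C5) are reversals of
#' an up (down) model signature by the single herb or the synergy
#' combination; C3/C6 are model dysregulations preserved under the
#' antagonism combination relative to control.
#'
#' @param antagonism_comparison `"vs_con"` (default) tests the antagonism
#'   group against control for C3/C6; `"vs_mod"` tests it against the model
#'   group instead.
#' @return named list of category rules, each a list of two
#'   (comparison, direction) requirements.
#' @keywords internal
category_rules <- function(antagonism_comparison = c("vs_con", "vs_mod")) {
  antagonism_comparison <- match.arg(antagonism_comparison)
  ant <- if (antagonism_comparison == "vs_con") "DJGC_antagonism_vs_Con" else "DJGC_antagonism_vs_Mod"
  list(
    C1 = list(c("Mod_vs_Con", "up"),   c("DJ_alone_vs_Mod", "down")),
    C2 = list(c("Mod_vs_Con", "up"),   c("DJGC_synergy_vs_Mod", "down")),
    C3 = list(c("Mod_vs_Con", "up"),   c(ant, "up")),
    C4 = list(c("Mod_vs_Con", "down"), c("DJ_alone_vs_Mod", "up")),
    C5 = list(c("Mod_vs_Con", "down"), c("DJGC_synergy_vs_Mod", "up")),
    C6 = list(c("Mod_vs_Con", "down"), c(ant, "down"))
  )
}

# comparison label convention: "A_vs_B" = test group A against reference B,
# so its log2FC is mean(A) - mean(B)
comparison_label <- function(res) paste0(res$test, "_vs_", res$reference)

#' Classify genes into the six combination-related categories
#'
#' A gene joins a category when it is a passing DEG with the stated
#' direction in both of the category's comparisons. Categories may overlap;
#' the union is de-duplicated.
#'
#' @param deg_results named list of [screen_degs()] results. Names must be
#'   `"<test>_vs_<reference>"`; the required comparisons are
#'   `Mod_vs_Con`, `DJ_alone_vs_Mod`, `DJGC_synergy_vs_Mod` and (depending
#'   on `antagonism_comparison`) `DJGC_antagonism_vs_Con` or
#'   `DJGC_antagonism_vs_Mod`.
#' @param antagonism_comparison see [category_rules()].
#' @return object of class `category_assignment`: list with `categories`
#'   (named list C1..C6 of gene vectors), `union` (deduplicated character
#'   vector), `rules` and `antagonism_comparison`.
#' @export
classify_combination_genes <- function(deg_results,
                                       antagonism_comparison = c("vs_con", "vs_mod")) {
  antagonism_comparison <- match.arg(antagonism_comparison)
  rules <- category_rules(antagonism_comparison)
  needed <- unique(unlist(lapply(rules, function(r) c(r[[1]][1], r[[2]][1]))))
  for (cmp in needed) {
    if (!cmp %in% names(deg_results)) stop("missing required comparison: ", cmp)
    res <- deg_results[[cmp]]
    if (!inherits(res, "deg_result")) stop(cmp, " is not a deg_result")
    if (comparison_label(res) != cmp) {
      stop("comparison ", cmp, " has swapped or mismatched group labels (",
           comparison_label(res), ")")
    }
  }
  directional <- function(cmp, dir) {
    tab <- deg_results[[cmp]]$table
    tab$gene[tab$passing & tab$direction == dir]
  }
  categories <- lapply(rules, function(r)
    sort(intersect(directional(r[[1]][1], r[[1]][2]),
                   directional(r[[2]][1], r[[2]][2]))))
  structure(list(categories = categories,
                 union = sort(unique(unlist(categories, use.names = FALSE))),
                 rules = rules,
                 antagonism_comparison = antagonism_comparison),
            class = "category_assignment")
}

#' @export
print.category_assignment <- function(x, ...) {
  cat("Combination-related gene categories (antagonism ",
      x$antagonism_comparison, "):\n", sep = "")
  for (cn in names(x$categories)) {
    cat(sprintf("  %s: %d gene(s)\n", cn, length(x$categories[[cn]])))
  }
  cat(sprintf("  union: %d unique gene(s); category sizes sum to %d\n",
              length(x$union), sum(lengths(x$categories))))
  invisible(x)
}

#' Per-gene category evidence table
#'
#' One row per (gene, category) with the two driving log2 fold changes and
#' p-values.
#'
#' @param assignment a `category_assignment`.
#' @param deg_results the same named list given to
#'   [classify_combination_genes()].
#' @return data frame with columns gene, category, comparison_1, log2fc_1,
#'   p_1, comparison_2, log2fc_2, p_2 (zero rows when nothing classified).
#' @export
category_report <- function(assignment, deg_results) {
  stopifnot(inherits(assignment, "category_assignment"))
  rows <- list()
  for (cn in names(assignment$categories)) {
    genes <- assignment$categories[[cn]]
    if (!length(genes)) next
    r <- assignment$rules[[cn]]
    t1 <- deg_results[[r[[1]][1]]]$table
    t2 <- deg_results[[r[[2]][1]]]$table
    i1 <- match(genes, t1$gene); i2 <- match(genes, t2$gene)
    rows[[cn]] <- data.frame(
      gene = genes, category = cn,
      comparison_1 = r[[1]][1], log2fc_1 = t1$log2fc[i1], p_1 = t1$p_value[i1],
      comparison_2 = r[[2]][1], log2fc_2 = t2$log2fc[i2], p_2 = t2$p_value[i2],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), category = character(),
                      comparison_1 = character(), log2fc_1 = numeric(),
                      p_1 = numeric(), comparison_2 = character(),
                      log2fc_2 = numeric(), p_2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
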
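#' Configuration for the synthetic five-group study generator
#'
#' The defaults emulate the design of the motivating study: five groups
#' (Con, Mod, DJ_alone, DJGC_synergy, DJGC_antagonism) of three pooled
#' subjects each, log2-scale expression with i.i.d. Gaussian noise, planted
#' model-vs-control differential genes of +/- `effect_size` log2 units, six
#' disjoint direction-reversal categories, a scale-free-ish interaction
#' table with planted hubs, and one planted linear signal axis connecting a
#' combination-related gene to a known therapeutic target through
#' interior hub genes.
#'
#' @param n_genes number of genes on the array (default 2000).
#' @param n_per_group samples per group (default 3).
#' @param seed integer seed fixing all randomness.
#' @param n_up,n_down planted up/down model-vs-control DEGs (defaults
#'   100/50).
#' @param effect_size planted shift in log2 units (default 2.5).
#' @param noise_sd per-sample Gaussian noise sd in log2 units (default 0.5).
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   levels.
#' @param category_counts named integer vector `C1..C6`; planted on
#'   disjoint gene sets, C1-C3 within the up genes, C4-C6 within the down
#'   genes (defaults 25/35/4/10/26/1).
#' @param n_targets size of the known-therapeutic-target list (default 30).
#' @param pa_m edges attached per step of the preferential-attachment
#'   background graph (default 2).
#' @param n_planted_hubs planted high-degree genes, including the axis
#'   interior (default 12).
#' @param hub_spokes high-score edges attached to each planted hub
#'   (default 30).
#' @param hub_core_prob probability of an edge between two planted hubs
#'   (default 0.5).
#' @param score_range_background,score_range_hub integer combined-score
#'   ranges (defaults 150-900 and 700-950).
#' @param axis_score combined score of the planted axis edges (default 999,
#'   above every other score so the axis survives the median threshold).
#' @param axis_length number of genes on the planted axis (default 5).
#' @param n_pathways pathway sets in the generated collection, including
#'   the one containing the axis (default 20).
#' @param pathway_size_range size range of the random pathway sets.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_genes = 2000, n_per_group = 3, seed = 1,
                             n_up = 100, n_down = 50,
                             effect_size = 2.5, noise_sd = 0.5,
                             baseline_mean = 7, baseline_sd = 1,
                             category_counts = c(C1 = 25, C2 = 35, C3 = 4,
                                                 C4 = 10, C5 = 26, C6 = 1),
                             n_targets = 30, pa_m = 2,
                             n_planted_hubs = 12, hub_spokes = 30,
                             hub_core_prob = 0.5,
                             score_range_background = c(150, 900),
                             score_range_hub = c(700, 950),
                             axis_score = 999, axis_length = 5,
                             n_pathways = 20,
                             pathway_size_range = c(10, 40)) {
  cfg <- list(n_genes = n_genes, n_per_group = n_per_group, seed = seed,
              n_up = n_up, n_down = n_down, effect_size = effect_size,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              category_counts = category_counts, n_targets = n_targets,
              pa_m = pa_m, n_planted_hubs = n_planted_hubs,
              hub_spokes = hub_spokes, hub_core_prob = hub_core_prob,
              score_range_background = score_range_background,
              score_range_hub = score_range_hub, axis_score = axis_score,
              axis_length = axis_length, n_pathways = n_pathways,
              pathway_size_range = pathway_size_range)
  cc <- cfg$category_counts
  if (!all(c("C1", "C2", "C3", "C4", "C5", "C6") %in% names(cc))) {
    stop("category_counts must be named C1..C6")
  }
  if (cfg$n_up + cfg$n_down > cfg$n_genes) stop("planted DEGs exceed n_genes")
  if (sum(cc[c("C1", "C2", "C3")]) > cfg$n_up) stop("C1+C2+C3 exceed n_up")
  if (sum(cc[c("C4", "C5", "C6")]) > cfg$n_down) stop("C4+C5+C6 exceed n_down")
  if (cfg$effect_size <= 0) stop("effect_size must be positive")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$n_per_group < 2) stop("n_per_group must be >= 2")
  if (cfg$axis_length < 2) stop("axis_length must be >= 2")
  structure(cfg, class = "synthetic_config")
}

group_levels <- function() c("Con", "Mod", "DJ_alone", "DJGC_synergy", "DJGC_antagonism")

gene_names <- function(n) sprintf("G%0*d", max(4L, nchar(n)), seq_len(n))
target_names <- function(n) sprintf("T%02d", seq_len(n))

#' Generate five-group expression data with planted ground truth
#'
#' Baseline log2 levels are drawn per gene; planted DEGs are shifted by
#' +/- `effect_size` in the model group. Category genes additionally follow
#' their direction-reversal pattern in the treatment groups: C1/C4 return
#' to baseline under the single herb, C2/C5 under the synergy combination,
#' and C3/C6 retain the model level under the antagonism combination. All
#' other planted DEGs persist at the model level under the single herb and
#' the synergy combination and return to baseline under antagonism; non-DEG
#' genes sit at baseline in every group. Output is a pure function of the
#' configuration (including its seed).
#'
#' @param config a [synthetic_config()].
#' @return list with `expr` (matrix, genes x samples), `groups` (named
#'   character vector) and `truth` (list with `planted_up`, `planted_down`,
#'   `categories`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  npg <- config$n_per_group
  genes <- gene_names(ng)
  grp <- rep(group_levels(), each = npg)
  samples <- paste(grp, rep(seq_len(npg), times = 5L), sep = "_")
  up_idx <- seq_len(config$n_up)
  down_idx <- config$n_up + seq_len(config$n_down)
  cc <- config$category_counts
  take <- function(pool, n, used) utils::head(setdiff(pool, used), n)
  used <- integer()
  cat_idx <- list()
  for (cn in c("C1", "C2", "C3")) {
    cat_idx[[cn]] <- take(up_idx, cc[[cn]], used)
    used <- c(used, cat_idx[[cn]])
  }
  for (cn in c("C4", "C5", "C6")) {
    cat_idx[[cn]] <- take(down_idx, cc[[cn]], used)
    used <- c(used, cat_idx[[cn]])
  }
  baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  eff <- config$effect_size
  deg_shift <- numeric(ng)
  deg_shift[up_idx] <- eff
  deg_shift[down_idx] <- -eff
  shift <- matrix(0, ng, 5L, dimnames = list(genes, group_levels()))
  shift[, "Mod"] <- deg_shift
  # default treatment behaviour of non-category DEGs
  shift[, "DJ_alone"] <- deg_shift
  shift[, "DJGC_synergy"] <- deg_shift
  # antagonism default: back to baseline (stays 0)
  shift[cat_idx$C1, "DJ_alone"] <- 0
  shift[cat_idx$C4, "DJ_alone"] <- 0
  shift[cat_idx$C2, "DJGC_synergy"] <- 0
  shift[cat_idx$C5, "DJGC_synergy"] <- 0
  shift[cat_idx$C3, "DJGC_antagonism"] <- eff
  shift[cat_idx$C6, "DJGC_antagonism"] <- -eff
  mu <- baseline + shift[, grp]
  expr <- mu + matrix(stats::rnorm(ng * length(samples), 0, config$noise_sd), ng)
  dimnames(expr) <- list(genes, samples)
  truth <- list(
    planted_up = genes[up_idx],
    planted_down = genes[down_idx],
    categories = lapply(cat_idx, function(ix) genes[ix])
  )
  list(expr = expr, groups = stats::setNames(grp, samples), truth = truth)
}

#' Generate the interaction table, target list and pathway collection
#'
#' The gene universe is the union of the planted DEGs and the known-target
#' list. A preferential-attachment background graph provides a heavy-tailed
#' degree distribution; planted hub genes (the axis interior plus further
#' non-category DEGs) receive `hub_spokes` extra high-score edges each and
#' a dense mutual core. The axis chain (combination-related endpoint,
#' interior hubs, known-target endpoint) is inserted with `axis_score`
#' edges, above every other score and therefore above any median threshold;
#' the two endpoints carry no other edges and all non-consecutive pairs of
#' axis genes are kept non-adjacent, which (for the default length of 5)
#' makes the planted chain the unique score-preferred shortest path between
#' the endpoints in the seed sub-network.
#'
#' @param config a [synthetic_config()].
#' @param truth the truth list from [generate_expression()].
#' @return list with `interactions` (data frame), `known_targets`
#'   (character), `pathways` (`gene_set_collection`) and `truth` (the input
#'   truth augmented with `planted_hubs`, `axis`, `axis_pathway` and
#'   `known_targets`).
#' @export
generate_network <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed((config$seed %% 99999989L) + 104729L)
  targets <- target_names(config$n_targets)
  degs <- c(truth$planted_up, truth$planted_down)
  category_genes <- unique(unlist(truth$categories, use.names = FALSE))
  universe <- c(degs, targets)

  # ---- axis genes -------------------------------------------------------
  axis <- NULL
  interior <- character()
  free_up <- setdiff(truth$planted_up, category_genes)
  if (length(category_genes) && config$n_targets >= 1L) {
    seed_a <- if (length(truth$categories$C2)) truth$categories$C2[[1L]] else category_genes[[1L]]
    seed_b <- targets[[1L]]
    n_int <- config$axis_length - 2L
    if (length(free_up) < n_int) stop("axis longer than available planted genes")
    interior <- utils::head(free_up, n_int)
    axis <- c(seed_a, interior, seed_b)
    # the axis interior also joins the known-target list: real signal axes
    # run through established targets, and this anchors the planted chain
    # in the network independently of screening noise on any one comparison
    targets <- c(targets, interior)
  }

  # ---- planted hubs -----------------------------------------------------
  hub_pool <- setdiff(free_up, interior)
  extra_hubs <- utils::head(hub_pool, max(0L, config$n_planted_hubs - length(interior)))
  hubs <- c(interior, extra_hubs)

  # ---- background preferential-attachment graph -------------------------
  seeds <- if (is.null(axis)) character() else c(axis[1L], axis[length(axis)])
  bg_genes <- setdiff(universe, seeds)
  edges <- list()
  rint <- function(n, range) sample(seq(range[1L], range[2L]), n, replace = TRUE)
  if (length(bg_genes) > config$pa_m) {
    pa <- igraph::sample_pa(length(bg_genes), power = 1, m = config$pa_m,
                            directed = FALSE)
    lab <- sample(bg_genes)
    el <- igraph::as_edgelist(pa)
    edges$background <- data.frame(
      node_a = lab[as.integer(el[, 1L])], node_b = lab[as.integer(el[, 2L])],
      combined_score = rint(nrow(el), config$score_range_background),
      stringsAsFactors = FALSE)
  }
  # hub spokes: disjoint partner pools keep spoke partners from linking
  # two different axis-interior genes
  if (length(hubs)) {
    spoke_pool <- sample(setdiff(bg_genes, hubs))
    spokes <- list()
    pool_pos <- 0L
    for (h in hubs) {
      k <- min(config$hub_spokes, length(spoke_pool))
      picks <- spoke_pool[((pool_pos + seq_len(k) - 1L) %% length(spoke_pool)) + 1L]
      pool_pos <- pool_pos + k
      spokes[[h]] <- data.frame(node_a = h, node_b = picks,
                                combined_score = rint(k, config$score_range_hub),
                                stringsAsFactors = FALSE)
    }
    edges$spokes <- do.call(rbind, spokes)
    if (length(hubs) > 1L) {
      pairs <- utils::combn(hubs, 2L)
      pick <- stats::runif(ncol(pairs)) < config$hub_core_prob
      if (any(pick)) {
        edges$core <- data.frame(node_a = pairs[1L, pick], node_b = pairs[2L, pick],
                                 combined_score = rint(sum(pick), config$score_range_hub),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, edges)
  if (is.null(tab)) tab <- data.frame(node_a = character(), node_b = character(),
                                      combined_score = numeric(), stringsAsFactors = FALSE)
  # drop any generated edge between non-consecutive axis genes, then insert
  # the chain itself with the top score
  if (!is.null(axis)) {
    on_axis_a <- match(tab$node_a, axis)
    on_axis_b <- match(tab$node_b, axis)
    chord <- !is.na(on_axis_a) & !is.na(on_axis_b)
    tab <- tab[!chord, , drop = FALSE]
    tab <- rbind(tab, data.frame(node_a = axis[-length(axis)], node_b = axis[-1L],
                                 combined_score = config$axis_score,
                                 stringsAsFactors = FALSE))
  }
  interactions <- suppressWarnings(canonicalize_interactions(tab))

  # ---- pathway collection ----------------------------------------------
  sets <- list()
  desc <- character()
  if (!is.null(axis)) {
    extra <- utils::head(setdiff(universe, axis), 3L)
    sets[["pathway_axis"]] <- unique(c(axis, extra))
    desc <- "synthetic pathway containing the planted signal axis"
  }
  n_random <- config$n_pathways - length(sets)
  for (i in seq_len(max(0L, n_random))) {
    size <- sample(seq(config$pathway_size_range[1L], config$pathway_size_range[2L]), 1L)
    sets[[sprintf("pathway_%02d", i)]] <- sample(universe, min(size, length(universe)))
    desc <- c(desc, "synthetic random pathway")
  }
  pathways <- gene_set_collection(sets, desc)

  truth$planted_hubs <- hubs
  truth$axis <- axis
  truth$axis_pathway <- if (is.null(axis)) NULL else "pathway_axis"
  truth$known_targets <- targets
  list(interactions = interactions, known_targets = targets,
       pathways = pathways, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Runs [generate_expression()] and [generate_network()] and optionally
#' writes every input file (expression TSV, group map, interaction TSV,
#' GMT, target list) plus `truth.json` to a directory.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional output directory.
#' @return list with `expr`, `groups`, `interactions`, `known_targets`,
#'   `pathways`, `truth` and `config`.
#' @export
simulate_study <- function(config = synthetic_config(), out_dir = NULL) {
  ex <- generate_expression(config)
  net <- generate_network(config, ex$truth)
  out <- list(expr = ex$expr, groups = ex$groups,
              interactions = net$interactions,
              known_targets = net$known_targets,
              pathways = net$pathways, truth = net$truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_table(out$expr, out$groups,
                           file.path(out_dir, "expression.tsv"),
                           file.path(out_dir, "groups.tsv"))
    write_interaction_table(out$interactions, file.path(out_dir, "interactions.tsv"))
    write_gmt(out$pathways, file.path(out_dir, "pathways.gmt"))
    writeLines(out$known_targets, file.path(out_dir, "known_targets.txt"))
    jsonlite::write_json(out$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  out
}
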
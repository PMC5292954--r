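default_config <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    synthetic = list(),
    inputs = list(expression = NULL, groups = NULL, interactions = NULL,
                  interaction_dialect = "tsv3col", id_map = NULL,
                  pathways = NULL, known_targets = NULL, probe_map = NULL),
    thresholds = list(fc = 1.0, p = 0.05, hub_multiplier = 2),
    deg_method = "student",
    antagonism_comparison = "vs_con",
    major_hub_scope = "full",
    mcl = list(inflation = 2.0, expansion = 2, prune_threshold = 1e-5,
               max_iter = 200, tol = 1e-8),
    axis = list(seed_a = NULL, seed_b = NULL, annotate_fraction = 0.8),
    out_dir = NULL
  )
}

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML file path or a list. Unknown keys (at the top level and
#' within nested sections) are rejected; missing keys receive defaults.
#' In `mode = "files"` every referenced input path must exist. The
#' validated configuration is idempotent: validating it again returns an
#' identical object.
#'
#' @param config path to a YAML file, or a (partial) configuration list.
#' @return object of class `pipeline_config` (a fully-defaulted list).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  stopifnot(is.list(config))
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merge_section <- function(name) {
    sec <- config[[name]]
    if (is.null(sec)) return(def[[name]])
    bad <- setdiff(names(sec), names(def[[name]]))
    if (length(bad)) stop("unknown key(s) in ", name, ": ", paste(bad, collapse = ", "))
    utils::modifyList(def[[name]], sec, keep.null = TRUE)
  }
  cfg <- def
  for (k in names(config)) {
    # single-bracket assignment keeps keys whose value is NULL
    cfg[k] <- if (k %in% c("inputs", "thresholds", "mcl", "axis")) list(merge_section(k))
              else config[k]
  }
  if (!cfg$mode %in% c("simulate", "files")) stop("mode must be 'simulate' or 'files'")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) stop("seed must be a single integer")
  cfg$seed <- as.integer(cfg$seed)
  th <- cfg$thresholds
  if (th$fc <= 0 || th$p <= 0 || th$hub_multiplier <= 0) {
    stop("thresholds (fc, p, hub_multiplier) must be positive")
  }
  if (!cfg$deg_method %in% c("student", "welch", "limma")) {
    stop("deg_method must be student, welch or limma")
  }
  if (!cfg$antagonism_comparison %in% c("vs_con", "vs_mod")) {
    stop("antagonism_comparison must be vs_con or vs_mod")
  }
  if (!cfg$major_hub_scope %in% c("full", "subnetwork")) {
    stop("major_hub_scope must be full or subnetwork")
  }
  if (cfg$mcl$inflation <= 1) stop("mcl inflation must exceed 1")
  if (cfg$mode == "files") {
    req <- c("expression", "groups", "interactions", "pathways", "known_targets")
    for (k in req) {
      p <- cfg$inputs[[k]]
      if (is.null(p)) stop("mode 'files' requires inputs$", k)
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  } else {
    cfg$synthetic <- do.call(synthetic_config,
                             utils::modifyList(cfg$synthetic,
                                               list(seed = cfg$seed)))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full target-axis inference pipeline
#'
#' Stages: load or simulate inputs; screen DEGs for every required
#' comparison; classify combination-related genes; build the three-class
#' interaction network (ascites-related = model-vs-control passing DEGs,
#' combination-related = classifier union, known targets = the list);
#' compute topology; select hubs; induce the hub subnetwork; Markov-cluster
#' it into modules; select major hubs; run pathway enrichment on the hubs;
#' extract the seed-anchored signal axis. Writes all artifact tables plus a
#' machine-readable run summary when `out_dir` is set. Given a fixed
#' configuration (and seed), the run is deterministic and the summary
#' byte-identical across reruns.
#'
#' @param config a `pipeline_config`, or anything accepted by
#'   [validate_config()].
#' @return object of class `run_summary`: list of per-stage counts and the
#'   stage result objects (in `$objects`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  dat <- stage("load_inputs", {
    if (cfg$mode == "simulate") {
      simulate_study(cfg$synthetic)
    } else {
      et <- read_expression_table(cfg$inputs$expression, cfg$inputs$groups,
                                  id_level = if (is.null(cfg$inputs$probe_map)) "gene" else "probe")
      expr <- et$expr
      if (!is.null(cfg$inputs$probe_map)) {
        pm <- utils::read.delim(cfg$inputs$probe_map, header = FALSE,
                                stringsAsFactors = FALSE)
        expr <- collapse_probes(expr, pm)
      }
      list(expr = expr, groups = et$groups,
           interactions = read_interaction_table(cfg$inputs$interactions,
                                                 dialect = cfg$inputs$interaction_dialect,
                                                 id_map = cfg$inputs$id_map),
           known_targets = read_gene_list(cfg$inputs$known_targets),
           pathways = read_gmt(cfg$inputs$pathways),
           truth = NULL)
    }
  })

  ant_cmp <- if (cfg$antagonism_comparison == "vs_con") {
    c("DJGC_antagonism", "Con")
  } else {
    c("DJGC_antagonism", "Mod")
  }
  comparisons <- list(
    Mod_vs_Con = c("Mod", "Con"),
    DJ_alone_vs_Mod = c("DJ_alone", "Mod"),
    DJGC_synergy_vs_Mod = c("DJGC_synergy", "Mod"))
  comparisons[[paste0(ant_cmp[1L], "_vs_", ant_cmp[2L])]] <- ant_cmp

  degs <- stage("deg_screen", {
    lapply(comparisons, function(cm) {
      screen_degs(dat$expr, dat$groups, reference = cm[2L], test = cm[1L],
                  fc_threshold = cfg$thresholds$fc, p_threshold = cfg$thresholds$p,
                  method = cfg$deg_method)
    })
  })

  assignment <- stage("classify",
    classify_combination_genes(degs, antagonism_comparison = cfg$antagonism_comparison))

  mvc <- degs$Mod_vs_Con$table
  roles <- list(
    ascites_related = mvc$gene[mvc$passing],
    combination_related = assignment$union,
    known_target = dat$known_targets)

  network <- stage("build_network", build_network(roles, dat$interactions))
  topology <- stage("topology", compute_topology(network))
  hubs <- stage("select_hubs", select_hubs(topology, cfg$thresholds$hub_multiplier))
  hub_net <- stage("hub_subnetwork", hub_subnetwork(network, hubs))
  modules <- stage("mcl", mcl_cluster(hub_net,
                                      inflation = cfg$mcl$inflation,
                                      expansion = cfg$mcl$expansion,
                                      prune_threshold = cfg$mcl$prune_threshold,
                                      max_iter = cfg$mcl$max_iter,
                                      tol = cfg$mcl$tol))
  mh_topology <- if (cfg$major_hub_scope == "full") topology else compute_topology(hub_net)
  major_hubs <- stage("major_hubs", select_major_hubs(mh_topology, hubs))

  universe <- rownames(dat$expr)
  hub_enrichment <- stage("enrichment", {
    in_univ <- intersect(as.character(hubs), canonicalize_symbols(universe))
    if (length(in_univ)) suppressWarnings(enrich(in_univ, dat$pathways, universe))
    else NULL
  })

  seed_a <- cfg$axis$seed_a
  seed_b <- cfg$axis$seed_b
  if (is.null(seed_a) && !is.null(dat$truth$axis)) seed_a <- dat$truth$axis[1L]
  if (is.null(seed_b) && !is.null(dat$truth$axis)) seed_b <- dat$truth$axis[length(dat$truth$axis)]
  axis <- if (is.null(seed_a) || is.null(seed_b)) {
    NULL
  } else {
    stage("extract_axis",
          extract_axis(network, major_hubs, seed_a, seed_b,
                       pathways = dat$pathways,
                       annotate_fraction = cfg$axis$annotate_fraction))
  }

  summary <- list(
    seed = cfg$seed,
    mode = cfg$mode,
    package_version = as.character(utils::packageVersion("herbnet")),
    degs = lapply(degs, function(d) list(
      passing = length(d$passing),
      up = sum(d$table$passing & d$table$direction == "up"),
      down = sum(d$table$passing & d$table$direction == "down"))),
    category_counts = lapply(assignment$categories, length),
    combination_union = length(assignment$union),
    score_threshold = igraph::graph_attr(network, "score_threshold"),
    network_nodes = igraph::vcount(network),
    network_edges = igraph::ecount(network),
    hub_count = length(hubs),
    median_degree = unname(attr(hubs, "median_degree")),
    hub_subnetwork_nodes = igraph::vcount(hub_net),
    hub_subnetwork_edges = igraph::ecount(hub_net),
    module_count = length(modules$modules),
    module_sizes = unname(lengths(modules$modules)),
    major_hub_count = length(major_hubs),
    axis = if (is.null(axis) || !axis$found) NULL else axis$genes,
    axis_pathways = if (is.null(axis) || !axis$found) NULL else axis$pathways,
    config = summarize_config(cfg)
  )

  objects <- list(data = dat, degs = degs, assignment = assignment,
                  network = network, topology = topology, hubs = hubs,
                  hub_net = hub_net, modules = modules,
                  major_hubs = major_hubs, hub_enrichment = hub_enrichment,
                  axis = axis)

  if (!is.null(cfg$out_dir)) {
    stage("write_outputs", write_pipeline_outputs(cfg, summary, objects))
  }
  structure(c(summary, list(objects = objects)), class = "run_summary")
}

# config echo for the run summary; output paths excluded so that summaries
# of identical analyses are byte-identical wherever they are written
summarize_config <- function(cfg) {
  keep <- unclass(cfg)
  keep$out_dir <- NULL
  keep$synthetic <- if (cfg$mode == "simulate") unclass(cfg$synthetic) else NULL
  keep
}

write_pipeline_outputs <- function(cfg, summary, objects) {
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(objects$degs)) {
    utils::write.table(objects$degs[[nm]]$table,
                       file.path(out, paste0("deg_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep <- category_report(objects$assignment, objects$degs)
  utils::write.table(rep, file.path(out, "combination_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(category_counts = summary$category_counts,
         union = summary$combination_union),
    file.path(out, "combination_summary.json"), auto_unbox = TRUE, digits = NA)
  net <- annotate_network(objects)
  write_network_tables(net, file.path(out, "network"))
  utils::write.table(
    data.frame(gene = names(objects$modules$membership),
               module = unname(objects$modules$membership)),
    file.path(out, "modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(objects$hub_enrichment)) {
    utils::write.table(objects$hub_enrichment, file.path(out, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(objects$axis)) {
    jsonlite::write_json(
      list(found = objects$axis$found, genes = objects$axis$genes,
           edges = objects$axis$edges, pathways = objects$axis$pathways),
      file.path(out, "axis.json"), auto_unbox = TRUE, null = "null", digits = NA)
  }
  jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out)
}

# copy topology / hub / module annotations onto the network vertices for
# the node-table export
annotate_network <- function(objects) {
  net <- objects$network
  topo <- objects$topology
  idx <- match(igraph::V(net)$name, topo$gene)
  net <- igraph::set_vertex_attr(net, "degree", value = topo$degree[idx])
  net <- igraph::set_vertex_attr(net, "betweenness", value = topo$betweenness[idx])
  net <- igraph::set_vertex_attr(net, "closeness", value = topo$closeness[idx])
  net <- igraph::set_vertex_attr(net, "kcore", value = topo$kcoreness[idx])
  net <- igraph::set_vertex_attr(net, "is_hub",
                                 value = igraph::V(net)$name %in% as.character(objects$hubs))
  net <- igraph::set_vertex_attr(net, "is_major_hub",
                                 value = igraph::V(net)$name %in% objects$major_hubs)
  mod <- objects$modules$membership[igraph::V(net)$name]
  net <- igraph::set_vertex_attr(net, "module", value = unname(mod))
  net
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ", mode ", x$mode, ")\n", sep = "")
  for (nm in names(x$degs)) {
    cat(sprintf("  %s: %d DEGs (%d up, %d down)\n", nm,
                x$degs[[nm]]$passing, x$degs[[nm]]$up, x$degs[[nm]]$down))
  }
  cat(sprintf("  combination-related union: %d (categories %s)\n",
              x$combination_union,
              paste(unlist(x$category_counts), collapse = "/")))
  cat(sprintf("  network: %d nodes, %d edges (score threshold %g)\n",
              x$network_nodes, x$network_edges, x$score_threshold))
  cat(sprintf("  hubs: %d (degree > %g x median %g); hub subnetwork %d/%d\n",
              x$hub_count, x$config$thresholds$hub_multiplier,
              x$median_degree, x$hub_subnetwork_nodes, x$hub_subnetwork_edges))
  cat(sprintf("  modules: %d (sizes %s); major hubs: %d\n",
              x$module_count, paste(x$module_sizes, collapse = ", "),
              x$major_hub_count))
  if (!is.null(x$axis)) {
    cat("  axis:", paste(x$axis, collapse = "-"), "\n")
  } else {
    cat("  axis: not extracted\n")
  }
  invisible(x)
}
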
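test_that("median score threshold keeps the boundary and restricts to role genes", {
  iact <- data.frame(node_a = c("A", "B", "C", "Zz"), node_b = c("B", "C", "A", "A"),
                     combined_score = c(400, 500, 900, 999))
  # Zz carries no role: its 999 edge is not a candidate
  net <- build_network(list(ascites_related = c("A", "B", "C"),
                            combination_related = NULL, known_target = NULL), iact)
  expect_equal(igraph::graph_attr(net, "score_threshold"), 500)
  expect_equal(igraph::ecount(net), 2L)          # 500 and 900 kept, 400 dropped
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))
  expect_false("Zz" %in% igraph::V(net)$name)

  # all scores equal: median equals every score, all edges kept
  same <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                     combined_score = c(700, 700))
  net2 <- build_network(list(ascites_related = c("A", "B", "C"),
                             combination_related = NULL, known_target = NULL), same)
  expect_equal(igraph::ecount(net2), 2L)

  expect_error(build_network(list(ascites_related = "Q", combination_related = NULL,
                                  known_target = NULL), iact), "no candidate")
})

test_that("raising the score threshold never adds edges", {
  set.seed(41)
  iact <- data.frame(node_a = sample(LETTERS[1:12], 60, replace = TRUE),
                     node_b = sample(LETTERS[1:12], 60, replace = TRUE),
                     combined_score = sample(100:999, 60))
  iact <- iact[iact$node_a != iact$node_b, ]
  roles <- list(ascites_related = LETTERS[1:12], combination_related = NULL,
                known_target = NULL)
  prev <- Inf
  for (thr in c(200, 400, 600, 800)) {
    n_edges <- igraph::ecount(build_network(roles, iact, score_threshold = thr))
    expect_lte(n_edges, prev)
    prev <- n_edges
  }
})

test_that("role flags are the union of memberships", {
  iact <- data.frame(node_a = "A", node_b = "B", combined_score = 500)
  net <- build_network(list(ascites_related = c("A", "B"),
                            combination_related = "A", known_target = "B"), iact)
  i <- match(c("A", "B"), igraph::V(net)$name)
  expect_equal(igraph::vertex_attr(net, "ascites_related")[i], c(TRUE, TRUE))
  expect_equal(igraph::vertex_attr(net, "combination_related")[i], c(TRUE, FALSE))
  expect_equal(igraph::vertex_attr(net, "known_target")[i], c(FALSE, TRUE))
})

test_that("triangle and path topologies match hand calculations", {
  tri <- igraph::make_graph(~ a - b, b - c, a - c)
  t1 <- compute_topology(tri)
  expect_equal(t1$degree, rep(2, 3))
  expect_equal(t1$betweenness, rep(0, 3))
  expect_equal(t1$closeness, rep(1, 3))
  expect_equal(t1$kcoreness, rep(2, 3))

  path <- igraph::make_graph(~ a - b, b - c, c - d)
  t2 <- compute_topology(path)
  expect_equal(t2$betweenness[match(c("b", "c"), t2$gene)], c(2, 2))
  expect_equal(t2$closeness[match("b", t2$gene)], 3 / 4)
  expect_equal(t2$kcoreness, rep(1, 4))
})

test_that("all four features match the brute-force oracle on random graphs", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    adj <- random_test_graph(n, runif(1, 0.1, 0.4))
    topo <- compute_topology(graph_from_adj(adj))
    oracle <- bf_topology(adj)
    ord <- match(rownames(adj), topo$gene)
    expect_equal(topo$degree[ord], unname(oracle$degree), label = paste("degree", i))
    expect_equal(topo$betweenness[ord], oracle$betweenness, tolerance = 1e-9,
                 label = paste("betweenness", i))
    expect_equal(topo$closeness[ord], oracle$closeness, tolerance = 1e-12,
                 label = paste("closeness", i))
    expect_equal(topo$kcoreness[ord], as.numeric(oracle$kcoreness),
                 label = paste("kcore", i))
  }
})

test_that("removing nodes below coreness k leaves minimum degree >= k", {
  set.seed(101)
  adj <- random_test_graph(18, 0.25)
  g <- graph_from_adj(adj)
  topo <- compute_topology(g)
  for (k in 1:max(topo$kcoreness)) {
    keep <- topo$gene[topo$kcoreness >= k]
    sub <- igraph::induced_subgraph(g, keep)
    if (igraph::vcount(sub) > 0) expect_gte(min(igraph::degree(sub)), k)
  }
})

test_that("hub selection uses strict doubling of the median degree", {
  # 3-regular graph: no node exceeds twice the median
  reg <- igraph::sample_k_regular(8, 3)
  igraph::V(reg)$name <- sprintf("R%d", 1:8)
  expect_length(select_hubs(compute_topology(reg)), 0L)

  # star: median degree 1, only the center exceeds 2
  star <- igraph::make_star(11, mode = "undirected")
  igraph::V(star)$name <- c("Center", sprintf("L%02d", 1:10))
  hubs <- select_hubs(compute_topology(star))
  expect_equal(as.character(hubs), "Center")
  expect_equal(attr(hubs, "median_degree"), 1)
})

test_that("hub subnetwork is the induced subgraph with isolated hubs dropped", {
  g <- igraph::make_graph(~ a - b, c - d, e - f)
  sub <- hub_subnetwork(g, c("a", "b", "c"))     # c is isolated among hubs
  expect_setequal(igraph::V(sub)$name, c("a", "b"))
  expect_equal(igraph::ecount(sub), 1L)
  all_sub <- hub_subnetwork(g, igraph::V(g)$name)
  expect_equal(igraph::ecount(all_sub), igraph::ecount(g))
  expect_error(hub_subnetwork(g, character()), "empty hub set")
})

test_that("major hubs require strict excess over all four feature medians", {
  # vertex-transitive cycle: every feature equals its median, strict > fails
  cyc <- igraph::make_ring(6)
  igraph::V(cyc)$name <- sprintf("C%d", 1:6)
  topo <- compute_topology(cyc)
  expect_length(select_major_hubs(topo, igraph::V(cyc)$name), 0L)

  # constructed graph with one dominant clique node: compare to brute force
  set.seed(55)
  adj <- random_test_graph(8, 0.35)
  adj[1, 2:6] <- 1L; adj[2:6, 1] <- 1L  # node 1 dominates
  g <- graph_from_adj(adj)
  topo2 <- compute_topology(g)
  hubs <- topo2$gene
  got <- select_major_hubs(topo2, hubs)
  oracle <- bf_topology(adj)
  meds <- vapply(oracle, median, 0)
  want <- rownames(adj)[oracle$degree > meds["degree"] &
                        oracle$betweenness > meds["betweenness"] &
                        oracle$closeness > meds["closeness"] &
                        oracle$kcoreness > meds["kcoreness"]]
  expect_setequal(as.character(got), want)
  expect_true(all(got %in% hubs))
})

test_that("axis extraction follows shortest paths with score-resolved ties", {
  # seeds directly connected: the axis is that single edge
  iact <- data.frame(node_a = c("Comb1", "Comb1", "Hub1"),
                     node_b = c("Tgt1", "Hub1", "Tgt1"),
                     combined_score = c(500, 500, 500))
  net <- build_network(list(ascites_related = "Hub1", combination_related = "Comb1",
                            known_target = "Tgt1"), iact)
  ax <- extract_axis(net, "Hub1", "Comb1", "Tgt1")
  expect_true(ax$found)
  expect_equal(ax$genes, c("Comb1", "Tgt1"))

  # two equal-length routes: the one with the higher minimum edge score wins
  iact2 <- data.frame(
    node_a = c("Comb1", "Hubhi", "Comb1", "Hublo"),
    node_b = c("Hubhi", "Tgt1", "Hublo", "Tgt1"),
    combined_score = c(900, 950, 980, 400))
  net2 <- build_network(list(ascites_related = c("Hubhi", "Hublo"),
                             combination_related = "Comb1",
                             known_target = "Tgt1"), iact2,
                        score_threshold = 0)
  ax2 <- extract_axis(net2, c("Hubhi", "Hublo"), "Comb1", "Tgt1")
  expect_equal(ax2$genes, c("Comb1", "Hubhi", "Tgt1"))
  expect_equal(min(ax2$edges$combined_score), 900)

  # non-major-hub intermediates are invisible to the axis search
  ax3 <- extract_axis(net2, "Hublo", "Comb1", "Tgt1")
  expect_equal(ax3$genes, c("Comb1", "Hublo", "Tgt1"))

  # disconnected seeds: reported, not an error
  ax4 <- extract_axis(net2, character(), "Comb1", "Tgt1")
  expect_false(ax4$found)
  expect_match(ax4$reason, "disconnected")

  # role flags on the seeds are enforced
  expect_error(extract_axis(net2, "Hubhi", "Hubhi", "Tgt1"), "combination_related")
  expect_error(extract_axis(net2, "Hubhi", "Comb1", "Hubhi"), "known_target")
})

test_that("axis pathway annotation honors the containment fraction", {
  iact <- data.frame(node_a = c("Comb1", "Hub1"), node_b = c("Hub1", "Tgt1"),
                     combined_score = c(800, 800))
  net <- build_network(list(ascites_related = "Hub1", combination_related = "Comb1",
                            known_target = "Tgt1"), iact)
  pw <- read_gmt(local({
    p <- tempfile(fileext = ".gmt")
    writeLines(c("full\taxis pathway\tComb1\tHub1\tTgt1\tOther",
                 "partial\tone gene\tHub1\tUnrelated"), p)
    p
  }))
  ax <- extract_axis(net, "Hub1", "Comb1", "Tgt1", pathways = pw,
                     annotate_fraction = 0.8)
  expect_equal(ax$pathways, "full")
})
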
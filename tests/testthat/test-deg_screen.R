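test_that("screening thresholds act on hand-built genes as specified", {
  # gene A: clear 2-unit shift, tiny spread -> passes
  # gene B: 0.8-unit shift -> fails the fold-change threshold
  # gene C: 1.5-unit shift but huge spread -> fails the p threshold
  expr <- rbind(
    A = c(0.00, 0.05, -0.05, 2.00, 2.05, 1.95),
    B = c(0.00, 0.05, -0.05, 0.80, 0.85, 0.75),
    C = c(0.00, 1.00, -1.00, 1.50, 4.00, -1.00))
  colnames(expr) <- paste0("S", 1:6)
  groups <- setNames(rep(c("Con", "Mod"), each = 3), colnames(expr))
  res <- screen_degs(expr, groups, reference = "Con", test = "Mod")
  expect_equal(res$passing, "A")
  expect_equal(res$table$direction, c("up", "up", "up"))
  # per-gene statistics agree with the classical t-test
  for (g in rownames(expr)) {
    tt <- t.test(expr[g, 4:6], expr[g, 1:3], var.equal = TRUE)
    row <- res$table[res$table$gene == g, ]
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-12, label = g)
    expect_equal(row$log2fc, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("identical group values yield zero passing DEGs", {
  expr <- matrix(rep(c(1, 2, 3), times = 4), nrow = 2, byrow = TRUE)
  dimnames(expr) <- list(c("G1", "G2"), paste0("S", 1:6))
  groups <- setNames(rep(c("Con", "Mod"), each = 3), colnames(expr))
  res <- screen_degs(expr, groups, "Con", "Mod")
  expect_length(res$passing, 0L)
})

test_that("vectorized statistics match per-gene t.test under both variance models", {
  set.seed(21)
  expr <- matrix(rnorm(50 * 8), 50, dimnames = list(sprintf("G%02d", 1:50),
                                                    paste0("S", 1:8)))
  expr[sample(length(expr), 12)] <- NA  # pairwise-complete handling
  groups <- setNames(rep(c("Con", "Mod"), each = 4), colnames(expr))
  for (method in c("student", "welch")) {
    res <- screen_degs(expr, groups, "Con", "Mod", method = method)
    for (g in rownames(expr)) {
      a <- expr[g, 1:4]; b <- expr[g, 5:8]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      row <- res$table[res$table$gene == g, ]
      if (length(a) < 2 || length(b) < 2) {
        expect_true(is.na(row$p_value))
        next
      }
      tt <- t.test(b, a, var.equal = (method == "student"))
      expect_equal(row$p_value, tt$p.value, tolerance = 1e-10,
                   label = paste(method, g))
      expect_equal(row$log2fc, mean(b) - mean(a), tolerance = 1e-12)
    }
  }
})

test_that("swapping reference and test negates log2FC and swaps directions", {
  set.seed(5)
  expr <- matrix(rnorm(40 * 6, 5, 1), 40,
                 dimnames = list(sprintf("G%02d", 1:40), paste0("S", 1:6)))
  groups <- setNames(rep(c("Con", "Mod"), each = 3), colnames(expr))
  ab <- screen_degs(expr, groups, "Con", "Mod")
  ba <- screen_degs(expr, groups, "Mod", "Con")
  expect_equal(ab$table$log2fc, -ba$table$log2fc)
  expect_equal(ab$table$p_value, ba$table$p_value)
  expect_equal(ab$table$direction,
               ifelse(ba$table$direction == "up", "down", "up"))
  expect_setequal(ab$passing, ba$passing)
})

test_that("passing count is monotone in both thresholds", {
  set.seed(9)
  expr <- matrix(rnorm(200 * 6, 0, 1.5), 200,
                 dimnames = list(sprintf("G%03d", 1:200), paste0("S", 1:6)))
  groups <- setNames(rep(c("Con", "Mod"), each = 3), colnames(expr))
  counts_fc <- vapply(c(0.25, 0.5, 1, 1.5), function(fc)
    length(screen_degs(expr, groups, "Con", "Mod", fc_threshold = fc)$passing), 0L)
  expect_true(all(diff(counts_fc) <= 0))
  counts_p <- vapply(c(0.2, 0.1, 0.05, 0.01), function(p)
    length(screen_degs(expr, groups, "Con", "Mod", p_threshold = p)$passing), 0L)
  expect_true(all(diff(counts_p) <= 0))
})

test_that("screen rejects degenerate group specifications", {
  expr <- matrix(0, 2, 3, dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  groups <- c(S1 = "Con", S2 = "Con", S3 = "Mod")
  expect_error(screen_degs(expr, groups, "Con", "Mod"), "fewer than 2")
  expect_error(screen_degs(expr, groups, "Con", "Nope"), "unknown group")
  expect_error(screen_degs(expr, groups, "Con", "Con"), "must differ")
})

test_that("probe collapse keeps the dominant probe and matches a brute-force oracle", {
  expr <- rbind(p1 = c(1, 1, 1), p2 = c(3, 3, 3), p3 = c(0.5, 0.2, 0.1))
  colnames(expr) <- paste0("S", 1:3)
  map <- data.frame(probe = c("p1", "p2"), gene = c("GeneX", "GeneX"))
  expect_message(out <- collapse_probes(expr, map), "1 unmapped")
  expect_equal(rownames(out), "Genex")
  expect_equal(unname(out[1, ]), c(3, 3, 3))
  expect_error(collapse_probes(expr, data.frame(probe = "zz", gene = "Y")),
               "no probes")

  set.seed(31)
  expr2 <- matrix(rnorm(10 * 4), 10,
                  dimnames = list(sprintf("pr%02d", 1:10), paste0("S", 1:4)))
  map2 <- data.frame(probe = rownames(expr2),
                     gene = sample(c("Ga", "Gb", "Gc"), 10, replace = TRUE))
  out2 <- collapse_probes(expr2, map2)
  for (g in unique(map2$gene)) {
    members <- map2$probe[map2$gene == g]
    best <- members[which.max(rowMeans(abs(expr2[members, , drop = FALSE])))]
    expect_equal(out2[g, ], expr2[best, ], label = g)
  }
})

test_that("DEG clustering merges by Euclidean distance with average linkage", {
  # two identical rows merge first at height zero
  expr <- rbind(A = c(0, 0), B = c(0, 0), C = c(5, 5))
  colnames(expr) <- c("S1", "S2")
  cl <- cluster_degs(expr)
  expect_equal(cl$gene_hclust$height[1], 0)
  expect_setequal(cl$gene_hclust$labels[-cl$gene_hclust$merge[1, ]], c("A", "B"))

  # distances 1, 2, sqrt(5): first merge at 1, then average linkage at (2+sqrt(5))/2
  expr2 <- rbind(A = c(0, 0), B = c(1, 0), C = c(1, 2))
  colnames(expr2) <- c("S1", "S2")
  h <- cluster_degs(expr2)$gene_hclust
  expect_equal(h$height, c(1, (2 + sqrt(5)) / 2), tolerance = 1e-12)

  expect_error(cluster_degs(expr2[1, , drop = FALSE]), ">=2")
})

test_that("sample dendrogram separates control from model when DEGs are planted", {
  cfg <- synthetic_config(seed = 3, n_genes = 400, n_up = 40, n_down = 20,
                          category_counts = c(C1 = 0, C2 = 0, C3 = 0,
                                              C4 = 0, C5 = 0, C6 = 0))
  dat <- generate_expression(cfg)
  res <- screen_degs(dat$expr, dat$groups, "Con", "Mod")
  keep <- names(dat$groups)[dat$groups %in% c("Con", "Mod")]
  cl <- cluster_degs(dat$expr[res$passing, keep])
  cut <- cutree(cl$sample_hclust, k = 2)
  expect_equal(length(unique(cut[grep("^Con", names(cut))])), 1L)
  expect_equal(length(unique(cut[grep("^Mod", names(cut))])), 1L)
  expect_true(cut[grep("^Con", names(cut))[1]] != cut[grep("^Mod", names(cut))[1]])
})
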
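scores3 <- tibble::tibble(chemical_id = c("c1", "c1", "c2"),
                          gene_symbol = c("g1", "g2", "g2"),
                          G = c(2, 1, 3))

test_that("the network keeps one weighted edge per scored pair above threshold", {
  net <- build_network(scores3, z_threshold = 0)
  expect_equal(igraph::ecount(net), 3)
  expect_equal(igraph::vcount(net), 4)
  expect_setequal(igraph::E(net)$weight, c(2, 1, 3))
  expect_true(igraph::bipartite_mapping(net)$res)

  net2 <- build_network(scores3, z_threshold = 2.5)
  expect_equal(igraph::ecount(net2), 1)
  expect_equal(igraph::vcount(net2), 2)
  expect_setequal(igraph::V(net2)$name, c("c2", "g2"))
})

test_that("54 fully scoring chemicals against 156 genes give 210 nodes", {
  scores <- tidyr::expand_grid(chemical_id = sprintf("chem%02d", 1:54),
                               gene_symbol = sprintf("g%03d", 1:156))
  scores$G <- 1
  net <- build_network(scores, z_threshold = 0)
  expect_equal(igraph::vcount(net), 210)
  expect_equal(igraph::ecount(net), 54 * 156)
})

test_that("a threshold excluding all edges warns and returns an empty network", {
  expect_warning(net <- build_network(scores3, z_threshold = 99), "excludes")
  expect_equal(igraph::ecount(net), 0)
})

test_that("edge filtering is monotone in the threshold", {
  set.seed(6)
  scores <- tidyr::expand_grid(chemical_id = paste0("c", 1:8),
                               gene_symbol = paste0("g", 1:6))
  scores$G <- rnorm(nrow(scores), 1, 1.5)
  thr <- seq(-2, 4, by = 0.5)
  counts <- vapply(thr, function(z) {
    suppressWarnings(igraph::ecount(build_network(scores, z)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # conservation: edge count equals the scored cells above threshold
  for (i in seq_along(thr)) {
    expect_equal(counts[i], sum(scores$G >= thr[i]))
  }
})

test_that("annotation labels genes and reports the unmapped remainder", {
  genes <- sprintf("g%03d", 1:156)
  scores <- tidyr::expand_grid(chemical_id = "c1", gene_symbol = genes)
  scores$G <- 1
  net <- build_network(scores, 0)

  full <- tibble::tibble(gene_symbol = genes, class_label = "steroid homeostasis")
  a1 <- annotate_nodes(net, full)
  expect_length(igraph::graph_attr(a1, "unmapped_genes"), 0)

  partial <- full[1:149, ]
  a2 <- annotate_nodes(net, partial)
  expect_length(igraph::graph_attr(a2, "unmapped_genes"), 7)

  a3 <- annotate_nodes(net, full[0, ])
  expect_length(igraph::graph_attr(a3, "unmapped_genes"), 156)
  expect_true(all(igraph::V(a3)$class_label[igraph::V(a3)$type] == "unmapped"))
})

test_that("degree and strength match a brute-force edge tally", {
  star <- tibble::tibble(chemical_id = "hub",
                         gene_symbol = paste0("g", 1:5), G = 1:5)
  ds <- degree_stats(build_network(star, 0))
  expect_equal(ds$degree[ds$node == "hub"], 5)
  expect_equal(ds$strength[ds$node == "hub"], 15)
  expect_true(all(ds$degree[ds$side == "gene"] == 1))
  expect_true(attr(ds, "summary")$chemical_promiscuity_exceeds_gene)

  suppressWarnings(empty <- build_network(star, 99))
  expect_equal(nrow(degree_stats(empty)), 0)

  set.seed(14)
  scores <- tidyr::expand_grid(chemical_id = paste0("c", 1:6),
                               gene_symbol = paste0("g", 1:7))
  scores$G <- rnorm(nrow(scores))
  kept <- scores[scores$G >= 0.3, ]
  ds2 <- degree_stats(build_network(scores, 0.3))
  for (ch in unique(kept$chemical_id)) {
    expect_equal(ds2$degree[ds2$node == ch], sum(kept$chemical_id == ch))
    expect_equal(ds2$strength[ds2$node == ch],
                 sum(kept$G[kept$chemical_id == ch]))
  }
})

test_that("the force layout is deterministic and pulls neighbors together", {
  net <- build_network(scores3, 0)
  l1 <- force_layout(net, seed = 42)
  l2 <- force_layout(net, seed = 42)
  expect_identical(l1$coords, l2$coords)
  expect_true(all(is.finite(l1$coords)))

  one <- build_network(scores3[1, ], 0)
  lo <- force_layout(one, seed = 1)
  expect_false(isTRUE(all.equal(lo$coords[1, ], lo$coords[2, ])))

  # two planted hubs joined by one edge: within-module distances shrink
  sc <- dplyr::bind_rows(
    tidyr::expand_grid(chemical_id = paste0("a", 1:4), gene_symbol = paste0("ga", 1:4)),
    tidyr::expand_grid(chemical_id = paste0("b", 1:4), gene_symbol = paste0("gb", 1:4)),
    tibble::tibble(chemical_id = "a1", gene_symbol = "gb1"))
  sc$G <- 1
  net2 <- build_network(sc, 0)
  lay <- force_layout(net2, seed = 7, iterations = 800)
  xy <- lay$coords
  within_a <- as.matrix(dist(xy[c(paste0("a", 1:4), paste0("ga", 1:4)), ]))
  between <- sqrt(rowSums((xy[paste0("a", 1:4), ] - xy[paste0("b", 1:4), ])^2))
  expect_lt(mean(within_a[upper.tri(within_a)]), mean(between))

  # the layout contract: edge endpoints are closer than random non-pairs
  el <- igraph::as_edgelist(net2)
  d_edge <- sqrt(rowSums((xy[el[, 1], , drop = FALSE] -
                          xy[el[, 2], , drop = FALSE])^2))
  set.seed(1)
  nm <- rownames(xy)
  rand <- replicate(nrow(el), sample(nm, 2))
  d_rand <- sqrt(rowSums((xy[rand[1, ], , drop = FALSE] -
                          xy[rand[2, ], , drop = FALSE])^2))
  expect_lt(mean(d_edge), mean(d_rand))
})

test_that("GraphML and GEXF exports round-trip nodes, weights and labels", {
  genes <- paste0("g", 1:6)
  scores <- tidyr::expand_grid(chemical_id = paste0("c", 1:4), gene_symbol = genes)
  set.seed(3)
  scores$G <- round(rnorm(nrow(scores), 1, 0.5), 6)
  scores <- scores[scores$G > 0.8, ]
  net <- annotate_nodes(build_network(scores, 0),
                        tibble::tibble(gene_symbol = genes[1:4],
                                       class_label = "neural activity"))
  lay <- force_layout(net, seed = 5)
  for (fmt in c("graphml", "gexf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(net, path, layout = lay, format = fmt)
    g2 <- import_graph(path, fmt)
    expect_setequal(igraph::V(g2)$name, igraph::V(net)$name)
    key <- function(g) {
      el <- igraph::as_edgelist(g)
      ord <- order(el[, 1], el[, 2])
      list(from = el[ord, 1], to = el[ord, 2],
           w = igraph::E(g)$weight[ord])
    }
    k1 <- key(net); k2 <- key(g2)
    expect_equal(k2$from, k1$from)
    expect_equal(k2$to, k1$to)
    expect_equal(k2$w, k1$w, tolerance = 1e-9)
    cls <- setNames(igraph::V(g2)$class_label, igraph::V(g2)$name)
    expect_equal(unname(cls[genes[1:4]]), rep("neural activity", 4))
    expect_true(igraph::bipartite_mapping(g2)$res)
  }
  # an empty network still exports to a valid, re-importable file
  suppressWarnings(empty <- build_network(scores, 99))
  for (fmt in c("graphml", "gexf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(empty, path, format = fmt)
    expect_equal(igraph::ecount(import_graph(path, fmt)), 0)
  }
  expect_error(export_graph(net, tempfile(), format = "dot"), "graphml")
})
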
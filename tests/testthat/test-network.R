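toy_ci <- function(edges_df) {
  edges_df$source <- "toy"
  build_consolidated_interactome(edges_df)
}

test_that("subnetwork induction keeps edges with both endpoints DE", {
  ci <- toy_ci(data.frame(gene_a = c("A", "B", "C", "E"),
                          gene_b = c("B", "C", "D", "F")))
  sub <- induce_subnetwork(ci, c("A", "B", "C", "E", "F"))
  expect_setequal(pair_keys <- paste(sub$induced_edges[, 1],
                                     sub$induced_edges[, 2]),
                  c("A B", "B C", "E F"))
  expect_setequal(sub$lcc_nodes, c("A", "B", "C"))
  expect_equal(sub$n_components, 2)
  expect_equal(sub$n_isolated_degs, 0)

  # DEGs disjoint from the interactome: empty result with a warning
  expect_warning(empty <- induce_subnetwork(ci, c("X", "Y")), "no interactome")
  expect_length(empty$induced_nodes, 0)
  expect_equal(empty$n_isolated_degs, 2)

  # all nodes DE: induced graph equals the interactome
  all_in <- induce_subnetwork(ci, ci$nodes)
  expect_equal(nrow(all_in$induced_edges), nrow(ci$edges))
  expect_setequal(all_in$induced_nodes, ci$nodes)
})

test_that("LCC agrees with a union-find oracle on 200 random graphs", {
  set.seed(303)
  for (rep in 1:200) {
    g <- random_graph(sample(2:50, 1), runif(1, 0.02, 0.2))
    got <- largest_connected_component(g$nodes, g$edges)
    expect_identical(got$lcc_nodes, uf_lcc(g$nodes, g$edges))
    keep <- g$edges[, 1] %in% got$lcc_nodes & g$edges[, 2] %in% got$lcc_nodes
    expect_equal(nrow(got$lcc_edges), sum(keep))
  }
})

test_that("LCC handles isolates and breaks ties by smallest symbol", {
  got <- largest_connected_component(c("A", "B", "C", "D", "E"),
                                     rbind(c("A", "B"), c("B", "C"),
                                           c("D", "E")))
  expect_identical(got$lcc_nodes, c("A", "B", "C"))
  # two equal components: the one containing the smallest symbol wins
  tie <- largest_connected_component(c("C", "D", "A", "B"),
                                     rbind(c("C", "D"), c("A", "B")))
  expect_identical(tie$lcc_nodes, c("A", "B"))
  # isolated single node is its own (trivial) component
  lone <- largest_connected_component("Z", matrix(character(0), ncol = 2))
  expect_identical(lone$lcc_nodes, "Z")
  expect_equal(nrow(lone$lcc_edges), 0)
})

test_that("modularity matches hand values and a recount oracle", {
  # all nodes in one module: Q = 0
  e <- clique_edges(c("A", "B", "C", "D"))
  one <- setNames(rep(0, 4), c("A", "B", "C", "D"))
  expect_equal(modularity_score(e, one), 0)
  # two disjoint 3-cliques split into the cliques: Q = 0.5
  e2 <- rbind(clique_edges(c("X1", "X2", "X3")),
              clique_edges(c("Y1", "Y2", "Y3")))
  asn <- setNames(c(0, 0, 0, 1, 1, 1), c("X1", "X2", "X3", "Y1", "Y2", "Y3"))
  expect_equal(modularity_score(e2, asn), 0.5)
  expect_equal(modularity_score(matrix(character(0), ncol = 2), asn), 0)
  # random graphs, random partitions: recount + igraph cross-checks
  set.seed(404)
  for (rep in 1:20) {
    g <- random_graph(sample(5:30, 1), 0.2)
    if (nrow(g$edges) == 0) next
    asn <- setNames(sample(0:2, length(g$nodes), replace = TRUE), g$nodes)
    q <- modularity_score(g$edges, asn)
    expect_equal(q, recount_modularity(g$edges, asn), tolerance = 1e-12)
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    ig <- ig + igraph::vertices(setdiff(g$nodes, igraph::V(ig)$name))
    expect_equal(q, igraph::modularity(ig, asn[igraph::V(ig)$name] + 1),
                 tolerance = 1e-12)
  }
})

test_that("spectral partition separates two bridged cliques exactly", {
  a <- sprintf("A%02d", 1:10); b <- sprintf("B%02d", 1:10)
  edges <- rbind(clique_edges(a), clique_edges(b), c("A01", "B01"))
  nodes <- sort(c(a, b))
  part <- spectral_partition(nodes, edges, min_module_size = 3)
  expect_equal(part$n_modules, 2)
  groups <- split(names(part$assignment), part$assignment)
  expect_true(setequal(groups[[1]], a) || setequal(groups[[1]], b))
  expect_equal(part$modularity,
               modularity_score(edges, part$assignment), tolerance = 1e-12)
})

test_that("splits that cannot help are refused", {
  # a single clique: no split improves modularity
  cl <- sprintf("C%02d", 1:12)
  part <- spectral_partition(cl, clique_edges(cl), min_module_size = 3)
  expect_equal(part$n_modules, 1)
  # 2-node path with min_module_size 3: size floor blocks any split
  part2 <- spectral_partition(c("A", "B"), rbind(c("A", "B")),
                              min_module_size = 3)
  expect_equal(part2$n_modules, 1)
})

test_that("partition is a disjoint cover with ids contiguous from 0", {
  spec <- synthetic_spec(seed = 5, n_genes = 200, block_sizes = rep(50, 4))
  gi <- generate_interactome(spec)
  lcc <- largest_connected_component(gi$ci$nodes,
                                     as.matrix(gi$ci$edges[, 1:2]))
  part <- spectral_partition(lcc$lcc_nodes, lcc$lcc_edges)
  expect_setequal(names(part$assignment), lcc$lcc_nodes)
  expect_setequal(unique(part$assignment), 0:(part$n_modules - 1))
  expect_equal(part$modularity,
               modularity_score(lcc$lcc_edges, part$assignment),
               tolerance = 1e-12)
  # determinism: identical inputs and seed give identical partitions
  again <- spectral_partition(lcc$lcc_nodes, lcc$lcc_edges)
  expect_identical(part, again)
})

test_that("planted blocks are recovered and recovery degrades as p_out rises", {
  aris <- vapply(c(0.01, 0.1, 0.3), function(p_out) {
    spec <- synthetic_spec(seed = 9, n_genes = 200, block_sizes = rep(50, 4),
                           p_in = 0.3, p_out = p_out)
    gi <- generate_interactome(spec)
    lcc <- largest_connected_component(gi$ci$nodes,
                                       as.matrix(gi$ci$edges[, 1:2]))
    part <- spectral_partition(lcc$lcc_nodes, lcc$lcc_edges)
    adjusted_rand_index(part$assignment,
                        gi$truth$block_labels[names(part$assignment)])
  }, numeric(1))
  expect_gte(aris[1], 0.9)
  expect_true(all(diff(aris) < 0))   # monotone degradation on the grid
})

test_that("adjusted Rand index matches the mclust reference", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(505)
  for (rep in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("target overlay flags the union intersected with network nodes", {
  lists <- list(alg1 = c("A", "B"), alg2 = c("B", "C"))
  ann <- overlay_targets(c("A", "B", "D"), lists)
  expect_identical(ann$predicted_targets, c("A", "B"))
  # appearing in every list still flags once
  ann3 <- overlay_targets(c("B"), c(lists, list(alg3 = "B")))
  expect_identical(ann3$predicted_targets, "B")
  # vote threshold of 2 keeps only multi-algorithm calls
  ann2 <- overlay_targets(c("A", "B", "D"), lists, vote_threshold = 2)
  expect_identical(ann2$predicted_targets, "B")
  expect_warning(overlay_targets(c("X"), lists), "no predicted target")
})

test_that("target lists read from per-algorithm files and 2-column TSV", {
  f1 <- write_lines_tmp(c("a", "b", "b"), ".txt")
  f2 <- write_lines_tmp(c("B", "c"), ".txt")
  lists <- read_target_lists(c(alg1 = f1, alg2 = f2))
  expect_identical(lists$alg1, c("A", "B"))
  expect_identical(lists$alg2, c("B", "C"))
  tsv <- write_lines_tmp(c("a\talg1", "b\talg1", "b\talg2"))
  lists2 <- read_target_lists(tsv)
  expect_identical(lists2, list(alg1 = c("A", "B"), alg2 = "B"))
})

test_that("annotated GraphML carries direction, module and target attributes", {
  ci <- toy_ci(data.frame(gene_a = c("A", "B", "C"), gene_b = c("B", "C", "A")))
  rows <- data.frame(gene = c("A", "B", "C"), log2fc = c(2, -2, 2),
                     pvalue = rep(0.001, 3))
  degs <- select_degs(rows)
  sub <- induce_subnetwork(ci, degs)
  ann <- overlay_targets(sub$induced_nodes, list(alg = "A"))
  path <- tempfile(fileext = ".graphml")
  write_network_graphml(sub, degs, partition = NULL, targets = ann, path = path)
  g <- igraph::read_graph(path, format = "graphml")
  v <- igraph::as_data_frame(g, "vertices")
  expect_setequal(v$name, c("A", "B", "C"))
  expect_identical(v$direction[v$name == "B"], "down")
  expect_true(v$predicted_target[v$name == "A"])
  expect_true(all(v$module == -1))
})
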
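test_that("degenerate edge probabilities give cliques or an error", {
  spec <- synthetic_spec(seed = 1, n_genes = 60, block_sizes = c(30, 30),
                         p_in = 1, p_out = 0, deg_blocks = 1)
  gi <- generate_interactome(spec)
  expect_equal(nrow(gi$ci$edges), 2 * choose(30, 2))  # two 30-cliques
  expect_equal(length(gi$ci$nodes), 60)
  lab <- gi$truth$block_labels
  same_block <- lab[gi$ci$edges$gene_a] == lab[gi$ci$edges$gene_b]
  expect_true(all(same_block))
  empty <- synthetic_spec(seed = 1, n_genes = 60, block_sizes = c(30, 30),
                          p_in = 0, p_out = 0, deg_blocks = 1)
  expect_error(generate_interactome(empty), "empty graph")
})

test_that("SBM edge counts sit within binomial moment bounds", {
  spec <- synthetic_spec(seed = 13, n_genes = 200, block_sizes = rep(50, 4),
                         p_in = 0.3, p_out = 0.01)
  gi <- generate_interactome(spec)
  lab <- gi$truth$block_labels
  within <- sum(lab[gi$ci$edges$gene_a] == lab[gi$ci$edges$gene_b])
  n_within_pairs <- 4 * choose(50, 2)
  mu <- n_within_pairs * 0.3
  sd <- sqrt(n_within_pairs * 0.3 * 0.7)
  expect_lt(abs(within - mu), 4 * sd)
  between <- nrow(gi$ci$edges) - within
  n_between_pairs <- choose(200, 2) - n_within_pairs
  mu_b <- n_between_pairs * 0.01
  expect_lt(abs(between - mu_b), 4 * sqrt(mu_b))
})

test_that("all-null DE tables pass the joint cut at the analytic rate", {
  spec <- synthetic_spec(seed = 3, deg_fraction = 0)
  gi <- generate_interactome(spec)
  gd <- generate_de_table(spec, gi$truth)
  expect_length(gd$truth$true_degs, 0)
  sel <- select_degs(gd$de_table, 1.5, 0.05)
  # independence of p ~ U(0,1) and log2fc ~ N(0, lfc_noise)
  rate <- 0.05 * 2 * pnorm(-log2(1.5) / spec$lfc_noise)
  n_pass <- length(deg_genes(sel))
  mu <- spec$n_genes * rate
  expect_lt(abs(n_pass - mu), 4 * sqrt(mu * (1 - rate)))
})

test_that("saturated strong signal is selected almost completely", {
  spec <- synthetic_spec(seed = 4, n_genes = 2000, block_sizes = rep(30, 4),
                         deg_fraction = 1, lfc_effect = 5, lfc_noise = 0.1)
  gd <- generate_de_table(spec, generate_interactome(spec)$truth)
  expect_length(gd$truth$true_degs, 2000)
  sel <- select_degs(gd$de_table, 1.5, 0.05)
  expect_gte(length(deg_genes(sel)) / 2000, 0.89)  # only Beta p-values fail
})

test_that("planted terms hold their fold and background terms are uniform", {
  spec <- synthetic_spec(seed = 8, n_genes = 5000, block_sizes = rep(40, 4),
                         deg_fraction = 0.2,
                         planted_terms = list(c(100, 4), c(200, 2)),
                         n_background_terms = 100,
                         term_size_range = c(20, 200))
  gd <- generate_de_table(spec, generate_interactome(spec)$truth)
  gs <- generate_gene_sets(spec, gd$truth)
  q <- length(gd$truth$true_degs) / spec$n_genes
  frac_deg <- vapply(gs$collection$sets, function(s) {
    mean(s %in% gd$truth$true_degs)
  }, numeric(1))
  # planted composition is exact by construction
  expect_equal(unname(frac_deg["PLANTED01"]), round(100 * 4 * q) / 100)
  expect_equal(unname(frac_deg["PLANTED02"]), round(200 * 2 * q) / 200)
  # background terms sample uniformly: mean DEG fraction near q
  bg <- frac_deg[startsWith(names(frac_deg), "BG")]
  expect_lt(abs(mean(bg) - q), 4 * sqrt(q * (1 - q) / sum(lengths(
    gs$collection$sets[startsWith(names(gs$collection$sets), "BG")]))))
  expect_setequal(gs$truth$enriched_terms, c("PLANTED01", "PLANTED02"))
})

test_that("target lists hit the stated fraction and union expectation", {
  spec <- synthetic_spec(seed = 6, n_genes = 500, block_sizes = rep(50, 4),
                         target_fraction = 0.2)
  gi <- generate_interactome(spec)
  gt <- generate_target_lists(spec, gi$truth)
  expect_length(gt$target_lists, 3)
  expect_true(all(lengths(gt$target_lists) == 40))   # 0.2 * 200
  # inclusion-exclusion: E|union| = n * (1 - (1 - f)^3)
  union_size <- length(unique(unlist(gt$target_lists)))
  expect_lt(abs(union_size - 200 * (1 - 0.8^3)), 15)
  # degenerate fractions
  spec0 <- synthetic_spec(seed = 6, n_genes = 500, block_sizes = rep(50, 4),
                          target_fraction = 0)
  expect_true(all(lengths(generate_target_lists(spec0, gi$truth)$target_lists) == 0))
  spec1 <- synthetic_spec(seed = 6, n_genes = 500, block_sizes = rep(50, 4),
                          target_fraction = 1)
  expect_true(all(vapply(generate_target_lists(spec1, gi$truth)$target_lists,
                         setequal, logical(1), names(gi$truth$block_labels))))
})

test_that("generators are byte-identical across runs for a fixed seed", {
  spec <- synthetic_spec(seed = 21, n_genes = 1000, block_sizes = rep(25, 4),
                         n_background_terms = 20, term_size_range = c(10, 50))
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  s1 <- write_synthetic_inputs(spec, d1)
  s2 <- write_synthetic_inputs(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # generator calls do not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_interactome(spec)); after <- runif(3)
  expect_identical(before, after)
})
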
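# Run `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for the synthetic study conditions
#'
#' Bundles every parameter of the synthetic generators. The defaults emulate
#' the statistical structure the pipeline assumes in the motivating study: a
#' gene universe of 20,949 symbols with ~19% differentially expressed
#' (foreground ~4,009 of 20,949), a modular interactome as a planted-partition
#' (stochastic-block-model) graph of 4 blocks of 50 genes with within-block
#' edge probability 0.30 and between-block probability 0.01, heavy-tailed
#' fold-change signal (|log2FC| centred on 2, spread 0.5; signal p-values
#' Beta(0.1, 10), null p-values uniform), a gene-set collection with planted
#' enriched terms, and three target-prediction lists each covering 20% of the
#' network genes.
#'
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @param n_genes universe size.
#' @param block_sizes integer vector of planted module sizes.
#' @param p_in,p_out within-/between-block edge probabilities (`p_in > p_out`
#'   for recoverable structure).
#' @param deg_fraction fraction of the universe made truly differentially
#'   expressed.
#' @param deg_blocks indices of blocks whose genes are all true DEGs (so the
#'   DEG subnetwork has planted module structure).
#' @param lfc_effect mean |log2 fold change| of true DEGs.
#' @param lfc_noise standard deviation of log2 fold changes (signal and null).
#' @param planted_terms list of `c(size, fold)` pairs: term size and the
#'   enrichment fold by which the term oversamples true DEGs.
#' @param n_background_terms number of uniformly drawn (null) terms.
#' @param term_size_range size range for background terms.
#' @param target_fraction fraction of network genes listed as predicted
#'   targets by each algorithm (lists drawn independently per algorithm).
#' @param algorithms names of the simulated target-prediction algorithms.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes = 20949L,
                           block_sizes = rep(50L, 4L),
                           p_in = 0.30, p_out = 0.01,
                           deg_fraction = 4009 / 20949,
                           deg_blocks = c(1L, 2L),
                           lfc_effect = 2, lfc_noise = 0.5,
                           planted_terms = list(c(100, 5), c(200, 3), c(300, 2)),
                           n_background_terms = 200L,
                           term_size_range = c(20L, 500L),
                           target_fraction = 0.2,
                           algorithms = c("targetscan", "pictar", "microt")) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            deg_fraction >= 0, deg_fraction <= 1,
            all(block_sizes > 0), sum(block_sizes) <= n_genes,
            target_fraction >= 0, target_fraction <= 1,
            all(deg_blocks %in% seq_along(block_sizes)))
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               block_sizes = as.integer(block_sizes), p_in = p_in,
               p_out = p_out, deg_fraction = deg_fraction,
               deg_blocks = as.integer(deg_blocks),
               lfc_effect = lfc_effect, lfc_noise = lfc_noise,
               planted_terms = planted_terms,
               n_background_terms = as.integer(n_background_terms),
               term_size_range = as.integer(term_size_range),
               target_fraction = target_fraction, algorithms = algorithms)
  class(spec) <- "synthetic_spec"
  spec
}

gene_ids <- function(n) sprintf("G%06d", seq_len(n))

#' Generate a planted-partition synthetic interactome
#'
#' Stochastic-block-model graph over the first `sum(block_sizes)` genes of the
#' universe: each within-block pair is an edge independently with probability
#' `p_in`, each between-block pair with `p_out`. Edge provenance is labelled
#' `"synthetic"`. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `ci` (a `consolidated_interactome`) and `truth` (list
#'   with `block_labels`, a named integer vector gene -> planted block).
#' @export
generate_interactome <- function(spec) {
  genes <- gene_ids(spec$n_genes)
  n_block <- sum(spec$block_sizes)
  members <- genes[seq_len(n_block)]
  labels <- stats::setNames(rep(seq_along(spec$block_sizes), spec$block_sizes),
                            members)
  pairs <- t(utils::combn(members, 2L))
  same <- labels[pairs[, 1]] == labels[pairs[, 2]]
  p <- ifelse(same, spec$p_in, spec$p_out)
  drawn <- with_seed(spec$seed, stats::runif(nrow(pairs)) < p)
  if (!any(drawn)) stop("spec yields an empty graph (no edge drawn)")
  records <- data.frame(gene_a = pairs[drawn, 1], gene_b = pairs[drawn, 2],
                        source = "synthetic", interaction_type = "",
                        stringsAsFactors = FALSE)
  list(ci = build_consolidated_interactome(records),
       truth = list(block_labels = labels))
}

#' Generate a synthetic differential-expression table
#'
#' Emulates a DESeq2-style results table over the whole universe. True DEGs
#' are every gene of the blocks in `spec$deg_blocks` plus uniformly drawn
#' extra genes (from outside the interactome blocks, so the planted DE
#' structure inside the network is exactly the chosen blocks) up to
#' `round(deg_fraction * n_genes)` in total; they get
#' `log2fc = sign * Normal(lfc_effect, lfc_noise)` with a random sign and
#' p-values from Beta(0.1, 10) (concentrated near 0). Null genes get
#' `log2fc ~ Normal(0, lfc_noise)` and uniform p-values. Deterministic given
#' `spec$seed` (offset so the draw is independent of the interactome's).
#'
#' @param spec a [synthetic_spec()].
#' @param truth the `truth` list from [generate_interactome()].
#' @return list with `de_table` (data.frame `gene`, `log2fc`, `pvalue`) and
#'   `truth` extended with `true_degs`.
#' @export
generate_de_table <- function(spec, truth) {
  genes <- gene_ids(spec$n_genes)
  n_deg <- round(spec$deg_fraction * spec$n_genes)
  block_degs <- names(truth$block_labels)[
    truth$block_labels %in% spec$deg_blocks]
  block_degs <- block_degs[seq_len(min(length(block_degs), n_deg))]
  tab <- with_seed(spec$seed + 1L, {
    pool <- setdiff(genes, names(truth$block_labels))
    n_extra <- max(0L, n_deg - length(block_degs))
    extra <- if (n_extra <= length(pool)) sample(pool, n_extra) else {
      # pool exhausted (deg_fraction near 1): spill into remaining block genes
      c(pool, sample(setdiff(names(truth$block_labels), block_degs),
                     n_extra - length(pool)))
    }
    true_degs <- sort(c(block_degs, extra))
    is_deg <- genes %in% true_degs
    lfc <- stats::rnorm(spec$n_genes, 0, spec$lfc_noise)
    sign_deg <- sample(c(-1, 1), sum(is_deg), replace = TRUE)
    lfc[is_deg] <- sign_deg *
      stats::rnorm(sum(is_deg), spec$lfc_effect, spec$lfc_noise)
    p <- stats::runif(spec$n_genes)
    p[is_deg] <- stats::rbeta(sum(is_deg), 0.1, 10)
    list(de = data.frame(gene = genes, log2fc = lfc, pvalue = p,
                         stringsAsFactors = FALSE),
         true_degs = true_degs)
  })
  truth$true_degs <- tab$true_degs
  list(de_table = tab$de, truth = truth)
}

#' Generate a synthetic gene-set collection with planted enrichment
#'
#' Background terms draw members uniformly from the universe. A planted term
#' of size `s` and fold `f` contains `round(s * min(1, f * q))` true DEGs
#' (where `q` is the realized true-DEG fraction of the universe) and null
#' genes otherwise, so its expected foreground ratio `k/n` is about `f` times
#' its background ratio `K/N`. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param truth truth list containing `true_degs`.
#' @return list with `collection` (a `gene_set_collection`) and `truth`
#'   extended with `enriched_terms`.
#' @export
generate_gene_sets <- function(spec, truth) {
  genes <- gene_ids(spec$n_genes)
  degs <- truth$true_degs
  nulls <- setdiff(genes, degs)
  q <- length(degs) / spec$n_genes
  collection <- with_seed(spec$seed + 2L, {
    sets <- list()
    for (i in seq_along(spec$planted_terms)) {
      s <- spec$planted_terms[[i]][1]
      f <- spec$planted_terms[[i]][2]
      n_hit <- round(s * min(1, f * q))
      sets[[sprintf("PLANTED%02d", i)]] <-
        sort(c(sample(degs, n_hit), sample(nulls, s - n_hit)))
    }
    sizes <- sample(seq(spec$term_size_range[1], spec$term_size_range[2]),
                    spec$n_background_terms, replace = TRUE)
    for (i in seq_len(spec$n_background_terms)) {
      sets[[sprintf("BG%04d", i)]] <- sort(sample(genes, sizes[i]))
    }
    sets
  })
  desc <- stats::setNames(
    ifelse(startsWith(names(collection), "PLANTED"),
           "planted enriched term", "background term"),
    names(collection))
  col <- list(sets = collection, descriptions = desc)
  class(col) <- "gene_set_collection"
  truth$enriched_terms <- grep("^PLANTED", names(collection), value = TRUE)
  list(collection = col, truth = truth)
}

#' Generate synthetic miRNA target-prediction lists
#'
#' Each algorithm independently samples `round(target_fraction * n)` of the
#' interactome (network) genes, so pairwise overlap is hypergeometric with
#' expectation `target_fraction^2 * n`. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param truth truth list containing `block_labels` (the network genes).
#' @return list with `target_lists` (named list algorithm -> sorted symbols)
#'   and `truth` extended with `target_genes`.
#' @export
generate_target_lists <- function(spec, truth) {
  members <- names(truth$block_labels)
  n_pick <- round(spec$target_fraction * length(members))
  lists <- with_seed(spec$seed + 3L, {
    stats::setNames(
      lapply(spec$algorithms, function(a) sort(sample(members, n_pick))),
      spec$algorithms)
  })
  truth$target_genes <- lists
  list(target_lists = lists, truth = truth)
}

#' Write every synthetic input in the formats the pipeline reads
#'
#' Emits an edge-list TSV, a DE table TSV, a GMT file, one symbol-per-line
#' target list per algorithm, and a ground-truth JSON, then returns the paths
#' plus the in-memory objects and ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (named: `interactome`, `de_table`, `gene_sets`,
#'   `targets` (named vector), `truth`), the generated objects, and `truth`.
#' @export
write_synthetic_inputs <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gi <- generate_interactome(spec)
  gd <- generate_de_table(spec, gi$truth)
  gs <- generate_gene_sets(spec, gd$truth)
  gt <- generate_target_lists(spec, gs$truth)
  truth <- gt$truth
  p_int <- file.path(dir, "interactome.tsv")
  write_interactome_tsv(gi$ci, p_int)
  p_de <- file.path(dir, "de_table.tsv")
  utils::write.table(
    data.frame(gene = gd$de_table$gene,
               log2FoldChange = gd$de_table$log2fc,
               pvalue = gd$de_table$pvalue),
    p_de, sep = "\t", quote = FALSE, row.names = FALSE)
  p_gmt <- file.path(dir, "gene_sets.gmt")
  write_gmt(gs$collection, p_gmt)
  p_targets <- vapply(spec$algorithms, function(a) {
    p <- file.path(dir, paste0("targets_", a, ".txt"))
    writeLines(gt$target_lists[[a]], p)
    p
  }, character(1))
  p_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(block_labels = as.list(truth$block_labels),
         true_degs = truth$true_degs,
         enriched_terms = truth$enriched_terms,
         target_genes = truth$target_genes),
    p_truth, auto_unbox = TRUE, pretty = TRUE)
  list(paths = list(interactome = p_int, de_table = p_de, gene_sets = p_gmt,
                    targets = p_targets, truth = p_truth),
       ci = gi$ci, de_table = gd$de_table, collection = gs$collection,
       target_lists = gt$target_lists, truth = truth)
}
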
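#' Configuration for a full pipeline run
#'
#' @param interactome character vector of interaction-source file paths.
#' @param de_table path to the differential-expression table.
#' @param gene_sets path to a GMT file.
#' @param targets named character vector of per-algorithm target-list paths
#'   (may be empty to skip the overlay).
#' @param outdir output directory for all artifacts.
#' @param fc_threshold,p_threshold DEG cut (defaults FC > 1.5, p < 0.05).
#' @param min_module_size spectral-partition size floor (default 5).
#' @param min_set,max_set gene-set size bounds for enrichment.
#' @param universe `"de_table"` (all genes in the DE table; default) or
#'   `"interactome"` (all interactome nodes).
#' @param vote_threshold target-overlay vote threshold (default 1 = union).
#' @param interactome_dialect parser dialect for the interaction files.
#' @param seed integer seed passed to seeded stages.
#' @return list of class `run_config`.
#' @export
run_config <- function(interactome, de_table, gene_sets, targets = character(0),
                       outdir, fc_threshold = 1.5, p_threshold = 0.05,
                       min_module_size = 5L, min_set = 10L, max_set = 500L,
                       universe = c("de_table", "interactome"),
                       vote_threshold = 1L,
                       interactome_dialect = "edge_tsv", seed = 1L) {
  universe <- match.arg(universe)
  paths <- c(interactome, de_table, gene_sets, targets)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  }
  cfg <- list(interactome = interactome, de_table = de_table,
              gene_sets = gene_sets, targets = targets, outdir = outdir,
              fc_threshold = fc_threshold, p_threshold = p_threshold,
              min_module_size = as.integer(min_module_size),
              min_set = as.integer(min_set), max_set = as.integer(max_set),
              universe = universe, vote_threshold = as.integer(vote_threshold),
              interactome_dialect = interactome_dialect,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full network-enrichment pipeline
#'
#' Executes, in order: consolidated-interactome assembly from the interaction
#' files, DEG selection from the DE table, DEG-subnetwork induction and
#' largest-connected-component extraction, spectral partitioning of the LCC
#' into modules, miRNA-target overlay, global over-representation analysis of
#' the DEG list, and per-module over-representation (foreground = one module's
#' genes, universe unchanged). Writes all artifacts under `config$outdir`:
#' `ci_edges.tsv`, `ci.graphml`, `degs.tsv`, `network.graphml`, `modules.tsv`,
#' `enrichment_global.tsv`, `enrichment_module<i>.tsv`, `run_summary.json`.
#'
#' Degenerate inputs (DEGs disjoint from the interactome, empty foreground)
#' produce warnings, empty downstream artifacts and a consistent summary, not
#' an error.
#'
#' @param config a [run_config()].
#' @return list of class `run_summary` with stage-by-stage counts, the config
#'   echo, and the in-memory stage results in `$stages`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  records <- do.call(rbind, lapply(config$interactome, read_interaction_file,
                                   dialect = config$interactome_dialect))
  ci <- build_consolidated_interactome(records)
  write_interactome_tsv(ci, file.path(config$outdir, "ci_edges.tsv"))
  write_interactome_graphml(ci, file.path(config$outdir, "ci.graphml"))

  de_rows <- read_de_table(config$de_table)
  degs <- select_degs(de_rows, config$fc_threshold, config$p_threshold)
  write_deg_table(degs, file.path(config$outdir, "degs.tsv"))

  subnet <- induce_subnetwork(ci, degs)

  partition <- NULL
  if (length(subnet$lcc_nodes) >= 2L) {
    partition <- spectral_partition(subnet$lcc_nodes, subnet$lcc_edges,
                                    min_module_size = config$min_module_size,
                                    seed = config$seed)
    write_module_table(partition, file.path(config$outdir, "modules.tsv"))
  }

  targets <- NULL
  if (length(config$targets) > 0L && length(subnet$induced_nodes) > 0L) {
    target_lists <- read_target_lists(config$targets)
    targets <- overlay_targets(subnet$induced_nodes, target_lists,
                               vote_threshold = config$vote_threshold)
  }
  if (length(subnet$induced_nodes) > 0L) {
    write_network_graphml(subnet, degs, partition, targets,
                          file.path(config$outdir, "network.graphml"))
  }

  collection <- read_gmt(config$gene_sets)
  universe <- if (config$universe == "de_table") de_rows$gene else ci$nodes
  global_enr <- enrich(deg_genes(degs), collection, universe,
                       min_set = config$min_set, max_set = config$max_set)
  write_enrichment_tsv(global_enr,
                       file.path(config$outdir, "enrichment_global.tsv"))

  module_enr <- list()
  if (!is.null(partition)) {
    for (mid in sort(unique(partition$assignment))) {
      fg <- names(partition$assignment)[partition$assignment == mid]
      enr <- suppressMessages(
        enrich(fg, collection, universe,
               min_set = config$min_set, max_set = config$max_set))
      module_enr[[as.character(mid)]] <- enr
      write_enrichment_tsv(
        enr, file.path(config$outdir, sprintf("enrichment_module%d.tsv", mid)))
    }
  }

  summary <- list(
    software = paste0("netora ",
                      as.character(utils::packageVersion("netora"))),
    config = config[setdiff(names(config), "outdir")],
    input_records = nrow(records),
    ci_nodes = length(ci$nodes),
    ci_edges = nrow(ci$edges),
    degs_up = length(degs$up),
    degs_down = length(degs$down),
    induced_nodes = length(subnet$induced_nodes),
    induced_edges = nrow(subnet$induced_edges),
    isolated_degs = subnet$n_isolated_degs,
    n_components = subnet$n_components,
    lcc_nodes = length(subnet$lcc_nodes),
    lcc_edges = nrow(subnet$lcc_edges),
    n_modules = if (is.null(partition)) 0L else partition$n_modules,
    modularity = if (is.null(partition)) NA_real_ else partition$modularity,
    flagged_targets = if (is.null(targets)) 0L
                      else length(targets$predicted_targets),
    tested_terms = nrow(global_enr),
    significant_terms = sum(global_enr$p_adjust < 0.05)
  )
  jsonlite::write_json(summary[setdiff(names(summary), "config")],
                       file.path(config$outdir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- c(summary, list(stages = list(
    ci = ci, degs = degs, subnet = subnet, partition = partition,
    targets = targets, global_enrichment = global_enr,
    module_enrichment = module_enr)))
  class(out) <- "run_summary"
  out
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Pipeline run: CI %d genes / %d edges; %d DEGs (%d up, %d down);\n",
    "  subnetwork %d genes / %d edges (%d components, %d isolated DEGs);\n",
    "  LCC %d genes / %d edges; %d modules (Q = %.3f); %d predicted targets;\n",
    "  %d terms tested, %d at adjusted p < 0.05\n"),
    x$ci_nodes, x$ci_edges, x$degs_up + x$degs_down, x$degs_up, x$degs_down,
    x$induced_nodes, x$induced_edges, x$n_components, x$isolated_degs,
    x$lcc_nodes, x$lcc_edges, x$n_modules,
    ifelse(is.na(x$modularity), 0, x$modularity),
    x$flagged_targets, x$tested_terms, x$significant_terms))
  invisible(x)
}
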
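#' Induce the DEG subnetwork from a consolidated interactome
#'
#' The induced subnetwork keeps exactly the interactome edges whose BOTH
#' endpoints are differentially expressed. DEGs with no surviving edge
#' (isolated in the induced graph, or absent from the interactome) are
#' excluded from the graph but counted in the result so run summaries can
#' report both conventions.
#'
#' @param ci a `consolidated_interactome`.
#' @param degs a `deg_selection`, or a character vector of gene symbols.
#' @return object of class `subnetwork_result`: list with `induced_nodes`,
#'   `induced_edges` (2-column matrix, rows sorted, `[,1] < [,2]`),
#'   `lcc_nodes`, `lcc_edges`, `n_components`, `n_isolated_degs`, and `graph`
#'   (igraph object of the induced subnetwork).
#' @export
induce_subnetwork <- function(ci, degs) {
  genes <- if (inherits(degs, "deg_selection")) deg_genes(degs) else
    sort(unique(normalize_symbol(degs)))
  genes <- genes[!is.na(genes)]
  in_deg <- ci$edges$gene_a %in% genes & ci$edges$gene_b %in% genes
  edges <- ci$edges[in_deg, c("gene_a", "gene_b"), drop = FALSE]
  if (nrow(edges) == 0L) {
    warning("no interactome edge has both endpoints differentially expressed")
    res <- list(induced_nodes = character(0),
                induced_edges = matrix(character(0), ncol = 2),
                lcc_nodes = character(0),
                lcc_edges = matrix(character(0), ncol = 2),
                n_components = 0L,
                n_isolated_degs = length(genes),
                graph = igraph::make_empty_graph(directed = FALSE))
    class(res) <- "subnetwork_result"
    return(res)
  }
  emat <- as.matrix(edges)
  dimnames(emat) <- NULL
  nodes <- sort(unique(c(emat[, 1], emat[, 2])))
  g <- igraph::graph_from_edgelist(emat, directed = FALSE)
  comp <- igraph::components(g)
  lcc <- largest_connected_component(nodes, emat)
  res <- list(induced_nodes = nodes,
              induced_edges = emat,
              lcc_nodes = lcc$lcc_nodes,
              lcc_edges = lcc$lcc_edges,
              n_components = comp$no,
              n_isolated_degs = length(setdiff(genes, nodes)),
              graph = g)
  class(res) <- "subnetwork_result"
  res
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat(sprintf(paste0("DEG subnetwork: %d genes, %d interactions; ",
                     "LCC %d genes, %d interactions (%d components, ",
                     "%d isolated DEGs)\n"),
              length(x$induced_nodes), nrow(x$induced_edges),
              length(x$lcc_nodes), nrow(x$lcc_edges),
              x$n_components, x$n_isolated_degs))
  invisible(x)
}

#' Largest connected component of a node/edge set
#'
#' Returns the component with the most nodes together with its induced edges.
#' Isolated nodes present in `nodes` count as singleton components. Ties for
#' the largest component are broken in favour of the component containing the
#' lexicographically smallest member symbol.
#'
#' @param nodes character vector of node names.
#' @param edges 2-column character matrix (or data.frame) of edges.
#' @return list with `lcc_nodes` (sorted) and `lcc_edges` (2-column matrix).
#' @export
largest_connected_component <- function(nodes, edges) {
  edges <- as.matrix(edges)
  if (length(nodes) == 0L) {
    return(list(lcc_nodes = character(0),
                lcc_edges = matrix(character(0), ncol = 2)))
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sort(nodes))
  if (nrow(edges) > 0L) g <- g + igraph::edges(t(edges))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component containing the smallest member symbol
    smallest <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    best <- best[which(smallest == min(smallest))[1]]
  }
  lcc_nodes <- sort(igraph::V(g)$name[comp$membership == best])
  keep <- if (nrow(edges) > 0L) {
    edges[, 1] %in% lcc_nodes & edges[, 2] %in% lcc_nodes
  } else logical(0)
  list(lcc_nodes = lcc_nodes,
       lcc_edges = edges[keep, , drop = FALSE])
}

#' Newman modularity of a node partition
#'
#' Computes `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` where `m` is the number of
#' edges, `e_c` the number of edges with both endpoints in module `c`, and
#' `d_c` the total degree of module `c`. Edges are unweighted. For an empty
#' edge set `Q` is defined as 0.
#'
#' @param edges 2-column character matrix of undirected edges.
#' @param assignment named vector (names = nodes) of module ids covering every
#'   endpoint.
#' @return modularity score (dimensionless, <= 1).
#' @export
modularity_score <- function(edges, assignment) {
  edges <- as.matrix(edges)
  m <- nrow(edges)
  if (m == 0L) return(0)
  ma <- assignment[edges[, 1]]
  mb <- assignment[edges[, 2]]
  if (anyNA(ma) || anyNA(mb)) stop("assignment does not cover all endpoints")
  mods <- unique(assignment)
  deg <- table(factor(c(edges[, 1], edges[, 2]), levels = names(assignment)))
  q <- 0
  for (c in mods) {
    e_c <- sum(ma == c & mb == c)
    d_c <- sum(deg[names(assignment)[assignment == c]])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  unname(q)
}

# Fiedler vector of the symmetric normalized Laplacian
# L = I - D^{-1/2} A D^{-1/2}, computed on a dense matrix with base eigen()
# (deterministic; `seed` is part of the interface for solver substitution but
# the dense symmetric solver needs no random start). The global sign is fixed
# so that the entry for the lexicographically smallest node with a non-zero
# entry is positive.
fiedler_vector <- function(nodes, edges) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  A <- matrix(0, n, n)
  if (nrow(edges) > 0L) {
    ij <- cbind(idx[edges[, 1]], idx[edges[, 2]])
    A[ij] <- 1
    A[ij[, 2:1, drop = FALSE]] <- 1
  }
  d <- rowSums(A)
  if (any(d == 0)) return(NULL)  # disconnected by isolates; caller handles
  dinv <- 1 / sqrt(d)
  L <- diag(n) - (dinv * A) * rep(dinv, each = n)
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  v <- eig$vectors[, n - 1L]  # second-smallest eigenvalue
  ord <- order(nodes)
  nz <- which(abs(v[ord]) > 1e-12)
  if (length(nz) > 0L && v[ord][nz[1]] < 0) v <- -v
  stats::setNames(v, nodes)
}

#' Spectral partitioning of a connected graph into dense modules
#'
#' Recursive two-way spectral bisection: at each step the Fiedler vector (the
#' eigenvector of the second-smallest eigenvalue of the symmetric normalized
#' Laplacian `L = I - D^{-1/2} A D^{-1/2}`) is computed for the current
#' subgraph and nodes are split by its sign, zero entries joining the positive
#' side. The sign split is then fine-tuned by a deterministic Kernighan-Lin
#' style sweep that moves single nodes between the two sides while total
#' Newman modularity increases (the same refinement Newman's leading-
#' eigenvector method applies after each bisection); without it a handful of
#' misplaced nodes at the first cut could never be corrected by later,
#' strictly nested, splits. A refined split is accepted only if it increases
#' total modularity of the whole partition and both sides have at least
#' `min_module_size` nodes; accepted sides are recursed on. The procedure is
#' deterministic: the dense
#' symmetric eigensolver needs no random initialization and the Fiedler
#' vector's global sign is fixed by requiring a non-negative entry for the
#' lexicographically smallest node. If the eigensolver fails on a subgraph,
#' that subgraph becomes a terminal module (with a message).
#'
#' @param lcc_nodes,lcc_edges a connected graph, e.g. the `lcc_nodes` /
#'   `lcc_edges` of [induce_subnetwork()].
#' @param min_module_size smallest admissible module (default 5).
#' @param seed integer; retained so callers can treat the partitioner as a
#'   seeded stochastic step, though the solver used here is deterministic.
#' @return object of class `module_partition`: list with `assignment` (named
#'   integer vector, module ids contiguous from 0, numbered by each module's
#'   smallest member symbol), `modularity`, `n_modules`.
#' @export
spectral_partition <- function(lcc_nodes, lcc_edges, min_module_size = 5L,
                               seed = 1L) {
  nodes <- sort(lcc_nodes)
  edges <- as.matrix(lcc_edges)
  stopifnot(length(nodes) >= 1L)
  assignment <- stats::setNames(rep(0L, length(nodes)), nodes)
  next_id <- 1L
  m <- nrow(edges)
  degree <- table(factor(c(edges[, 1], edges[, 2]), levels = nodes))

  # Greedy single-node sweeps between the two sides of a proposed split,
  # accepting any move with a positive global-modularity delta; other modules
  # are untouched, so the delta depends only on the two sides. Deterministic:
  # nodes are scanned in lexicographic order until a full pass is quiet.
  refine_split <- function(members, in_neg, sub_edges) {
    adj <- split(c(sub_edges[, 2], sub_edges[, 1]),
                 c(sub_edges[, 1], sub_edges[, 2]))
    d_side <- c(sum(degree[members[!in_neg]]), sum(degree[members[in_neg]]))
    for (pass in 1:50) {
      moved <- FALSE
      for (i in seq_along(members)) {
        v <- members[i]
        nb <- adj[[v]]
        side_v <- in_neg[i] + 1L            # 1 = pos, 2 = neg
        e_same <- sum(in_neg[match(nb, members)] == in_neg[i])
        e_other <- length(nb) - e_same
        d_v <- degree[[v]]
        dq <- (e_other - e_same) / m -
          d_v * (d_side[3L - side_v] - d_side[side_v] + d_v) / (2 * m^2)
        if (dq > 1e-12) {
          in_neg[i] <- !in_neg[i]
          d_side[side_v] <- d_side[side_v] - d_v
          d_side[3L - side_v] <- d_side[3L - side_v] + d_v
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    in_neg
  }

  bisect <- function(members) {
    if (length(members) < 2L * min_module_size) return(invisible(NULL))
    sub_edges <- edges[edges[, 1] %in% members & edges[, 2] %in% members, ,
                       drop = FALSE]
    if (nrow(sub_edges) == 0L) return(invisible(NULL))
    v <- tryCatch(fiedler_vector(members, sub_edges), error = function(e) NULL)
    if (is.null(v)) {
      message("eigen-solver failed on a ", length(members),
              "-node subgraph; kept as one module")
      return(invisible(NULL))
    }
    in_neg <- unname(v[members] < 0)  # zero entries join the positive side
    in_neg <- refine_split(members, in_neg, sub_edges)
    pos <- members[!in_neg]
    neg <- members[in_neg]
    if (length(pos) < min_module_size || length(neg) < min_module_size) {
      return(invisible(NULL))
    }
    old_q <- modularity_score(edges, assignment)
    trial <- assignment
    trial[neg] <- next_id
    new_q <- modularity_score(edges, trial)
    if (new_q <= old_q) return(invisible(NULL))
    assignment <<- trial
    next_id <<- next_id + 1L
    bisect(sort(pos))
    bisect(sort(neg))
    invisible(NULL)
  }

  bisect(nodes)
  # relabel ids contiguously from 0, ordered by smallest member symbol
  reps <- vapply(split(names(assignment), assignment), min, character(1))
  relabel <- stats::setNames(seq_along(reps) - 1L, names(sort(reps)))
  assignment <- stats::setNames(
    as.integer(relabel[as.character(assignment)]), names(assignment))
  part <- list(assignment = assignment,
               modularity = modularity_score(edges, assignment),
               n_modules = length(unique(assignment)))
  class(part) <- "module_partition"
  part
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules over %d nodes, modularity Q = %.4f\n",
              x$n_modules, length(x$assignment), x$modularity))
  invisible(x)
}

#' Read miRNA target-prediction lists
#'
#' Each algorithm's predictions come either as one file with one symbol per
#' line, or as a single 2-column TSV (`symbol`, `algorithm`).
#'
#' @param paths named character vector of per-algorithm file paths
#'   (names = algorithm labels), or a single unnamed path to a 2-column TSV.
#' @return named list algorithm -> sorted character vector of normalized
#'   symbols.
#' @export
read_target_lists <- function(paths) {
  if (is.null(names(paths)) && length(paths) == 1L) {
    tab <- utils::read.table(paths, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("2-column TSV (symbol, algorithm) expected")
    syms <- normalize_symbol(tab[[1]])
    return(lapply(split(syms, tab[[2]]), function(s) sort(unique(s[!is.na(s)]))))
  }
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("per-algorithm paths must be named by algorithm")
  }
  lapply(as.list(paths), function(p) {
    s <- normalize_symbol(readLines(p, warn = FALSE))
    sort(unique(s[!is.na(s)]))
  })
}

#' Overlay predicted miRNA targets on network nodes
#'
#' A node is flagged as a predicted target if it appears in at least
#' `vote_threshold` of the per-algorithm prediction lists (default 1, i.e. the
#' union — "reported by one of three algorithms").
#'
#' @param nodes character vector of network node symbols.
#' @param target_lists named list algorithm -> character vector of symbols,
#'   e.g. from [read_target_lists()].
#' @param vote_threshold minimum number of algorithms that must report a gene.
#' @return object of class `target_annotation`: list with `predicted_targets`
#'   (sorted, subset of `nodes`) and `per_algorithm` (each intersected with
#'   `nodes`).
#' @export
overlay_targets <- function(nodes, target_lists, vote_threshold = 1L) {
  stopifnot(length(target_lists) >= 1L, vote_threshold >= 1L)
  per_alg <- lapply(target_lists, function(s) {
    sort(intersect(normalize_symbol(s), nodes))
  })
  votes <- table(unlist(per_alg))
  flagged <- sort(names(votes)[votes >= vote_threshold])
  if (length(flagged) == 0L) {
    warning("no predicted target overlaps the network nodes")
  }
  ann <- list(predicted_targets = flagged, per_algorithm = per_alg)
  class(ann) <- "target_annotation"
  ann
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions of the same items,
#' corrected for chance; 1 means identical partitions, 0 is the chance level.
#' Used to score recovery of planted modules.
#'
#' @param a,b vectors of labels over the same items (matched by position, or
#'   by names when both are named).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b), !anyNA(a), !anyNA(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Write the annotated network as GraphML
#'
#' Node attributes mirror the published figure semantics: `direction`
#' (`"up"`/`"down"`), `module` (id from the spectral partition, -1 for nodes
#' outside the partition), `predicted_target` (logical).
#'
#' @param subnet a `subnetwork_result`.
#' @param degs a `deg_selection`.
#' @param partition a `module_partition` (over the LCC) or NULL.
#' @param targets a `target_annotation` or NULL.
#' @param path output path.
#' @export
write_network_graphml <- function(subnet, degs, partition = NULL,
                                  targets = NULL, path) {
  g <- subnet$graph
  nm <- igraph::V(g)$name
  igraph::V(g)$direction <- ifelse(nm %in% degs$up, "up",
                                   ifelse(nm %in% degs$down, "down", "none"))
  mod <- rep(-1L, length(nm))
  if (!is.null(partition)) {
    hit <- nm %in% names(partition$assignment)
    mod[hit] <- partition$assignment[nm[hit]]
  }
  igraph::V(g)$module <- mod
  igraph::V(g)$predicted_target <-
    if (is.null(targets)) FALSE else nm %in% targets$predicted_targets
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write module membership as TSV
#'
#' Columns `gene`, `module`.
#'
#' @param partition a `module_partition`.
#' @param path output path.
#' @export
write_module_table <- function(partition, path) {
  tab <- data.frame(gene = names(partition$assignment),
                    module = unname(partition$assignment))
  tab <- tab[order(tab$module, tab$gene), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
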
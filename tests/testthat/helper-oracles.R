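# Independent brute-force oracles, kept deliberately naive and separate from
# the package's own code paths.

# Upper-tail hypergeometric by exhaustive enumeration with exact choose().
enum_hyper_tail <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Connected components by union-find.
uf_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (NROW(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges[i, 1]); rb <- find(edges[i, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# LCC by enumeration over union-find components, with the same tie rule.
uf_lcc <- function(nodes, edges) {
  comps <- uf_components(nodes, edges)
  sizes <- lengths(comps)
  best <- comps[sizes == max(sizes)]
  mins <- vapply(best, min, character(1))
  sort(best[[which(mins == min(mins))[1]]])
}

# Benjamini-Hochberg by the literal step-up definition.
stepup_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cands <- vapply(rank_i:m, function(j) m * p[ord[j]] / j, numeric(1))
    adj[i] <- min(1, cands)
  }
  adj
}

# Modularity by direct edge/degree recount, independent of the package.
recount_modularity <- function(edges, assignment) {
  m <- NROW(edges)
  if (m == 0) return(0)
  q <- 0
  for (mod in unique(assignment)) {
    members <- names(assignment)[assignment == mod]
    e_c <- sum(edges[, 1] %in% members & edges[, 2] %in% members)
    d_c <- sum(edges[, 1] %in% members) + sum(edges[, 2] %in% members)
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Erdos-Renyi random graph as a character edge matrix (loop-free, simple).
random_graph <- function(n, p) {
  nodes <- sprintf("N%02d", seq_len(n))
  if (n < 2) return(list(nodes = nodes, edges = matrix(character(0), ncol = 2)))
  pairs <- t(utils::combn(nodes, 2))
  list(nodes = nodes, edges = pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE])
}

# Small clique edge list helper.
clique_edges <- function(members) t(utils::combn(members, 2))

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
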
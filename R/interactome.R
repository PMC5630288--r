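#' Read an interaction-source file
#'
#' Parses one exported interaction file into a data frame of raw interaction
#' records (one per data line). Two dialects are supported:
#'
#' * `"edge_tsv"` — tab-separated `geneA geneB [source] [type]`; a header line
#'   is auto-detected by vocabulary (e.g. `geneA`, `gene_b`, `source`). When
#'   the file carries no source column, `default_source` is used.
#' * `"mitab_lite"` — a minimal PSI-MITAB-like tab-separated layout. Gene
#'   symbols are taken from the alias columns (`alias_cols`, 1-based; PSI-MITAB
#'   2.5 puts interactor aliases in columns 5 and 6), preferring alias entries
#'   tagged `(gene name)`; the source-database column (`source_col`, MITAB
#'   column 13) is parsed from its parenthesised text when present. Full
#'   controlled-vocabulary MITAB parsing is out of scope.
#'
#' Malformed lines (too few columns, or no extractable symbol) are skipped and
#' counted in a single warning; they are never fatal. An unreadable file or a
#' file yielding zero parseable records is an error.
#'
#' @param path file path.
#' @param dialect `"edge_tsv"` or `"mitab_lite"`.
#' @param default_source source label used when the file has no source column.
#' @param alias_cols length-2 integer vector of alias column indices
#'   (`mitab_lite` only).
#' @param source_col source-database column index (`mitab_lite` only).
#' @return data.frame with columns `gene_a`, `gene_b`, `source`,
#'   `interaction_type` (raw, un-normalized symbols).
#' @export
read_interaction_file <- function(path, dialect = c("edge_tsv", "mitab_lite"),
                                  default_source = NULL,
                                  alias_cols = c(5L, 6L), source_col = 13L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("interaction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (is.null(default_source)) {
    default_source <- sub("\\.[^.]*$", "", basename(path))
  }
  recs <- switch(dialect,
    edge_tsv = parse_edge_tsv(lines, default_source),
    mitab_lite = parse_mitab_lite(lines, alias_cols, source_col, default_source)
  )
  if (recs$n_malformed > 0L) {
    warning(sprintf("%s: skipped %d malformed line(s)", basename(path),
                    recs$n_malformed))
  }
  if (nrow(recs$records) == 0L) {
    stop("no parseable interaction records in ", path)
  }
  recs$records
}

header_vocab <- c("genea", "geneb", "gene_a", "gene_b", "gene1", "gene2",
                  "symbola", "symbolb", "interactora", "interactorb",
                  "source", "type", "from", "to")

parse_edge_tsv <- function(lines, default_source) {
  if (length(lines) == 0L) {
    return(list(records = empty_records(), n_malformed = 0L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1]]))
  if (any(first %in% header_vocab)) fields <- fields[-1L]
  ok <- vapply(fields, function(f) length(f) >= 2L &&
                 nzchar(trimws(f[1])) && nzchar(trimws(f[2])), logical(1))
  n_malformed <- sum(!ok)
  fields <- fields[ok]
  get <- function(i, default) vapply(fields, function(f) {
    if (length(f) >= i && nzchar(trimws(f[i]))) trimws(f[i]) else default
  }, character(1))
  records <- data.frame(
    gene_a = vapply(fields, function(f) trimws(f[1]), character(1)),
    gene_b = vapply(fields, function(f) trimws(f[2]), character(1)),
    source = if (length(fields)) get(3L, default_source) else character(0),
    interaction_type = if (length(fields)) get(4L, "") else character(0),
    stringsAsFactors = FALSE
  )
  list(records = records, n_malformed = n_malformed)
}

# First alias tagged "(gene name)", else the value of the first alias entry.
mitab_symbol <- function(field) {
  parts <- strsplit(field, "|", fixed = TRUE)[[1]]
  vals <- sub("^[^:]*:", "", parts)
  tag <- grepl("\\(gene name\\)", parts)
  vals <- sub("\\(.*\\)$", "", vals)
  if (any(tag)) vals[tag][1] else if (length(vals)) vals[1] else NA_character_
}

mitab_source <- function(field, default_source) {
  m <- regmatches(field, regexpr("\\(([^)]+)\\)", field))
  if (length(m) && nzchar(m)) gsub("[()]", "", m[1]) else default_source
}

parse_mitab_lite <- function(lines, alias_cols, source_col, default_source) {
  if (length(lines) == 0L) {
    return(list(records = empty_records(), n_malformed = 0L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(lines[1])
  if (startsWith(first, "#id") || grepl("alias", first)) fields <- fields[-1L]
  need <- max(alias_cols)
  rows <- lapply(fields, function(f) {
    if (length(f) < need) return(NULL)
    a <- mitab_symbol(f[alias_cols[1]])
    b <- mitab_symbol(f[alias_cols[2]])
    if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) return(NULL)
    src <- if (length(f) >= source_col) {
      mitab_source(f[source_col], default_source)
    } else default_source
    data.frame(gene_a = a, gene_b = b, source = src, interaction_type = "",
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  records <- if (any(keep)) do.call(rbind, rows[keep]) else empty_records()
  list(records = records, n_malformed = sum(!keep))
}

empty_records <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             source = character(0), interaction_type = character(0),
             stringsAsFactors = FALSE)
}

#' Build a consolidated interactome from raw interaction records
#'
#' Merges interaction records (possibly from many source databases) into one
#' undirected, deduplicated gene-symbol graph with per-edge source provenance —
#' the "consolidated interactome" (CI) that downstream subnetwork induction
#' runs against. Symbols are normalized with [normalize_symbol()]; records with
#' an unusable symbol are dropped, self-loops are removed, reversed duplicates
#' of the same unordered pair collapse to a single edge whose provenance is the
#' union of source labels. All edges are undirected, untyped and unweighted;
#' the free-text interaction type is kept only in provenance export.
#'
#' @param records data.frame with columns `gene_a`, `gene_b`, `source`
#'   (and optionally `interaction_type`), e.g. rbind-ed output of
#'   [read_interaction_file()] over several files.
#' @return an object of class `consolidated_interactome`: list with
#'   `edges` (data.frame `gene_a`, `gene_b`, `sources` comma-joined, sorted so
#'   `gene_a < gene_b`), `nodes` (sorted character vector), `provenance`
#'   (named list pair-key -> character vector of sources), and `graph`
#'   (the corresponding [igraph::graph] object).
#' @export
build_consolidated_interactome <- function(records) {
  stopifnot(all(c("gene_a", "gene_b", "source") %in% names(records)))
  a <- normalize_symbol(records$gene_a)
  b <- normalize_symbol(records$gene_b)
  src <- as.character(records$source)
  keep <- !is.na(a) & !is.na(b) & a != b
  a <- a[keep]; b <- b[keep]; src <- src[keep]
  if (length(a) == 0L) stop("no edges survive normalization and self-loop removal")
  key <- pair_key(a, b)
  prov <- lapply(split(src, key), function(s) sort(unique(s)))
  keys <- sort(names(prov))
  prov <- prov[keys]
  ends <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
  edges <- data.frame(
    gene_a = ends[, 1], gene_b = ends[, 2],
    sources = vapply(prov, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ci <- list(
    edges = edges,
    nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
    provenance = prov,
    graph = igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                          directed = FALSE)
  )
  class(ci) <- "consolidated_interactome"
  ci
}

#' @export
print.consolidated_interactome <- function(x, ...) {
  cat(sprintf("Consolidated interactome: %d genes, %d interactions, %d source(s)\n",
              length(x$nodes), nrow(x$edges),
              length(unique(unlist(x$provenance)))))
  invisible(x)
}

#' Query edge membership and provenance (order-insensitive)
#'
#' @param ci a `consolidated_interactome`.
#' @param u,v gene symbols (raw; normalized before lookup).
#' @return character vector of source labels (length zero if the edge is
#'   absent).
#' @export
edge_provenance <- function(ci, u, v) {
  key <- pair_key(normalize_symbol(u), normalize_symbol(v))
  p <- ci$provenance[[key]]
  if (is.null(p)) character(0) else p
}

#' Write the consolidated interactome as canonical edge-list TSV
#'
#' Columns `gene_a`, `gene_b`, `sources` (comma-joined), pairs sorted; the file
#' round-trips through [read_interaction_file()] +
#' [build_consolidated_interactome()] to an identical graph.
#'
#' @param ci a `consolidated_interactome`.
#' @param path output path.
#' @export
write_interactome_tsv <- function(ci, path) {
  utils::write.table(ci$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the consolidated interactome as GraphML
#'
#' @param ci a `consolidated_interactome`.
#' @param path output path.
#' @export
write_interactome_graphml <- function(ci, path) {
  g <- ci$graph
  ekey <- pair_key(igraph::ends(g, igraph::E(g))[, 1],
                   igraph::ends(g, igraph::E(g))[, 2])
  igraph::E(g)$sources <- vapply(ci$provenance[ekey], paste, character(1),
                                 collapse = ",")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
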
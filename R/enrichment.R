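#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `term`, `description`,
#' then member symbols. Members are normalized with [normalize_symbol()] and
#' deduplicated; malformed lines (fewer than 3 fields, or no usable member)
#' are skipped with a warning. Zero parseable sets is an error.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: list with `sets`
#'   (named list term -> character vector of members) and `descriptions`
#'   (named character vector term -> description).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parsed <- lapply(fields, function(f) {
    if (length(f) < 3L) return(NULL)
    members <- sort(unique(stats::na.omit(normalize_symbol(f[-(1:2)]))))
    if (length(members) == 0L) return(NULL)
    list(term = trimws(f[1]), description = trimws(f[2]), members = members)
  })
  keep <- !vapply(parsed, is.null, logical(1))
  if (sum(!keep) > 0L) {
    warning(sprintf("%s: skipped %d malformed GMT line(s)", basename(path),
                    sum(!keep)))
  }
  parsed <- parsed[keep]
  if (length(parsed) == 0L) stop("no parseable gene sets in ", path)
  terms <- vapply(parsed, `[[`, character(1), "term")
  col <- list(sets = stats::setNames(lapply(parsed, `[[`, "members"), terms),
              descriptions = stats::setNames(
                vapply(parsed, `[[`, character(1), "description"), terms))
  class(col) <- "gene_set_collection"
  col
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(tm) {
    paste(c(tm, collection$descriptions[[tm]], collection$sets[[tm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric p-value for over-representation
#'
#' Probability of observing at least `k` annotated genes in a foreground of
#' size `n` drawn without replacement from a universe of `N` genes of which
#' `K` are annotated: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Computed
#' with [stats::phyper()]'s log-gamma based survival function, never naive
#' factorials. `k`, `n`, `K`, `N` are the counts printed as GeneRatio (`k/n`)
#' and BgRatio (`K/N`) in over-representation output tables.
#'
#' @param k foreground hits.
#' @param n foreground size.
#' @param K background (universe) hits.
#' @param N universe size.
#' @return p-value in `[0, 1]`; vectorized over its arguments.
#' @examples
#' hypergeometric_pvalue(138, 4009, 342, 20949)  # 5.21e-20
#' @export
hypergeometric_pvalue <- function(k, n, K, N) {
  if (any(k < 0 | K > N | n > N | k > pmin(n, K))) {
    stop("require 0 <= k <= min(n, K), K <= N, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adjusted_i = min over ranks >= rank(i) of
#' (m * p_j / rank_j)`, capped at 1, returned in the input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Storey q-values with a single-lambda null-proportion estimate
#'
#' `q_i = pi0_hat * BH_i` where `pi0_hat = min(1, mean(p > lambda) /
#' (1 - lambda))` at `lambda = 0.5`. With fewer than 10 p-values the estimate
#' is unstable and `pi0_hat` falls back to 1 (q-values then equal the BH
#' values). By construction q-values never exceed their BH counterparts and
#' are monotone non-decreasing in p-value rank.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param lambda tuning point for the null-proportion estimate (default 0.5).
#' @return q-values, same length and order as the input.
#' @export
storey_qvalues <- function(pvalues, lambda = 0.5) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1), lambda > 0, lambda < 1)
  pi0 <- if (length(pvalues) < 10L) 1 else
    min(1, mean(pvalues > lambda) / (1 - lambda))
  pi0 * bh_adjust(pvalues)
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set for over-representation in a foreground list with the
#' upper-tail hypergeometric test, relative to a stated gene universe.
#' Foreground genes outside the universe are dropped (with a message); each
#' term set is intersected with the universe and only terms whose resulting
#' size `K` lies in `[min_set, max_set]` are tested. BH adjustment and Storey
#' q-values are computed across all tested terms. Records are sorted by
#' p-value, ties broken by term id.
#'
#' @param foreground character vector of gene symbols (e.g. the DEG list or
#'   one module's genes).
#' @param collection a `gene_set_collection`.
#' @param universe character vector of background symbols (e.g. all genes in
#'   the DE table).
#' @param min_set,max_set admissible term sizes after universe intersection
#'   (defaults 10 and 500, conventional ORA bounds).
#' @return data.frame of class `enrichment_result` with columns `term`,
#'   `description`, `k`, `n`, `K`, `N`, `gene_ratio`, `bg_ratio`, `pvalue`,
#'   `p_adjust`, `qvalue`.
#' @export
enrich <- function(foreground, collection, universe,
                   min_set = 10L, max_set = 500L) {
  stopifnot(min_set <= max_set)
  universe <- sort(unique(stats::na.omit(normalize_symbol(universe))))
  fg <- unique(stats::na.omit(normalize_symbol(foreground)))
  outside <- setdiff(fg, universe)
  if (length(outside) > 0L) {
    message(length(outside), " foreground gene(s) outside the universe dropped")
    fg <- intersect(fg, universe)
  }
  empty <- enrichment_frame(character(0), character(0), integer(0),
                            integer(0), integer(0), integer(0))
  if (length(fg) == 0L) {
    warning("empty foreground after universe intersection")
    return(empty)
  }
  N <- length(universe)
  n <- length(fg)
  sets_u <- lapply(collection$sets, intersect, universe)
  K <- lengths(sets_u)
  keep <- K >= min_set & K <= max_set
  if (!any(keep)) {
    warning("no gene set within the size bounds after universe intersection")
    return(empty)
  }
  sets_u <- sets_u[keep]
  K <- K[keep]
  k <- vapply(sets_u, function(s) length(intersect(s, fg)), integer(1))
  res <- enrichment_frame(names(sets_u),
                          unname(collection$descriptions[names(sets_u)]),
                          k, n, K, N)
  res <- res[order(res$pvalue, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

enrichment_frame <- function(term, description, k, n, K, N) {
  p <- if (length(term)) hypergeometric_pvalue(k, rep(n[1], length(k)),
                                               K, rep(N[1], length(k)))
       else numeric(0)
  res <- data.frame(term = term, description = description,
                    k = as.integer(k), n = as.integer(rep(n[1], length(k))),
                    K = as.integer(K), N = as.integer(rep(N[1], length(k))),
                    gene_ratio = if (length(term)) paste0(k, "/", n[1]) else character(0),
                    bg_ratio = if (length(term)) paste0(K, "/", N[1]) else character(0),
                    pvalue = p,
                    p_adjust = bh_adjust(p),
                    qvalue = storey_qvalues(p),
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Write an enrichment result as TSV
#'
#' The column set mirrors published over-representation tables —
#' `Description`, `GeneRatio`, `BgRatio`, `pvalue`, `p.adjust`, `qvalue` —
#' plus `term` and the raw counts `k`, `n`, `K`, `N`. Probabilities are
#' rendered in scientific notation with 3 significant digits and an uppercase
#' E (e.g. `5.21E-20`).
#'
#' @param res an `enrichment_result`.
#' @param path output path.
#' @export
write_enrichment_tsv <- function(res, path) {
  sci <- function(x) toupper(formatC(x, format = "e", digits = 2))
  out <- data.frame(Description = res$description,
                    GeneRatio = res$gene_ratio,
                    BgRatio = res$bg_ratio,
                    pvalue = sci(res$pvalue),
                    p.adjust = sci(res$p_adjust),
                    qvalue = sci(res$qvalue),
                    term = res$term,
                    k = res$k, n = res$n, K = res$K, N = res$N,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
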
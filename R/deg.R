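#' Read a differential-expression results table
#'
#' Loads a DESeq2-style results table (TSV or CSV, sniffed from the header
#' line) with configurable column names. Rows with a missing p-value or
#' log2 fold change are dropped with a message; duplicate gene symbols are
#' resolved by keeping the row with the smallest p-value. Gene symbols are
#' normalized with [normalize_symbol()].
#'
#' @param path file path.
#' @param gene_col,lfc_col,p_col column names (defaults match DESeq2 output:
#'   `gene`, `log2FoldChange`, `pvalue`).
#' @return data.frame with columns `gene`, `log2fc`, `pvalue`, one row per
#'   gene.
#' @export
read_de_table <- function(path, gene_col = "gene", lfc_col = "log2FoldChange",
                          p_col = "pvalue") {
  if (!file.exists(path)) stop("DE table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(gene_col, lfc_col, p_col), names(tab))
  if (length(missing_cols) > 0L) {
    stop("DE table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  rows <- data.frame(gene = normalize_symbol(tab[[gene_col]]),
                     log2fc = as.numeric(tab[[lfc_col]]),
                     pvalue = as.numeric(tab[[p_col]]),
                     stringsAsFactors = FALSE)
  bad <- is.na(rows$gene) | is.na(rows$log2fc) | is.na(rows$pvalue) |
    !is.finite(rows$log2fc)
  if (any(bad)) {
    message(sum(bad), " DE row(s) dropped (missing gene, fold change or p-value)")
    rows <- rows[!bad, , drop = FALSE]
  }
  if (nrow(rows) == 0L) stop("DE table has no usable rows")
  stopifnot(all(rows$pvalue >= 0 & rows$pvalue <= 1))
  # duplicates: keep the smallest p-value per gene
  rows <- rows[order(rows$gene, rows$pvalue), , drop = FALSE]
  rows <- rows[!duplicated(rows$gene), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Select differentially expressed genes
#'
#' Applies the joint fold-change / p-value cut that seeds the subnetwork and
#' the enrichment foreground. `fc_threshold` is a linear fold change applied
#' symmetrically on the log2 scale with strict inequalities: a gene is up if
#' `log2fc > log2(fc_threshold)` and `pvalue < p_threshold`, down if
#' `log2fc < -log2(fc_threshold)` and `pvalue < p_threshold`. A gene sitting
#' exactly at either threshold is excluded.
#'
#' The default cut is FC > 1.5, p < 0.05; FC > 1.25 is the other cut used for
#' the enrichment foreground in the motivating study and is reachable by
#' argument.
#'
#' @param rows data.frame from [read_de_table()] (`gene`, `log2fc`, `pvalue`).
#' @param fc_threshold linear fold-change cutoff, > 1.
#' @param p_threshold unadjusted p-value cutoff in (0, 1].
#' @return object of class `deg_selection`: list with character vectors `up`
#'   and `down` (disjoint), the thresholds, and `table` (the selected rows
#'   with a `direction` column).
#' @export
select_degs <- function(rows, fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(fc_threshold > 1, p_threshold > 0, p_threshold <= 1)
  l2 <- log2(fc_threshold)
  sig <- rows$pvalue < p_threshold
  up <- rows$gene[sig & rows$log2fc > l2]
  down <- rows$gene[sig & rows$log2fc < -l2]
  if (length(up) + length(down) == 0L) {
    warning("no genes pass FC > ", fc_threshold, ", p < ", p_threshold)
  }
  tab <- rows[rows$gene %in% c(up, down), , drop = FALSE]
  tab$direction <- ifelse(tab$gene %in% up, "up", "down")
  sel <- list(up = sort(up), down = sort(down),
              fc_threshold = fc_threshold, p_threshold = p_threshold,
              table = tab)
  class(sel) <- "deg_selection"
  sel
}

#' @export
print.deg_selection <- function(x, ...) {
  cat(sprintf("DEG selection (FC > %g, p < %g): %d up, %d down\n",
              x$fc_threshold, x$p_threshold, length(x$up), length(x$down)))
  invisible(x)
}

#' All selected genes (up and down)
#' @param sel a `deg_selection`.
#' @return sorted character vector.
#' @export
deg_genes <- function(sel) sort(c(sel$up, sel$down))

#' Write a DEG selection as TSV
#'
#' Columns `gene`, `direction`, `log2fc`, `pvalue`.
#'
#' @param sel a `deg_selection`.
#' @param path output path.
#' @export
write_deg_table <- function(sel, path) {
  tab <- sel$table[order(sel$table$gene), c("gene", "direction", "log2fc", "pvalue")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
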
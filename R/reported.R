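#' Reported over-representation rows for the miR-21 inhibition DEG list
#'
#' The published enrichment table for genes differentially expressed after
#' miR-21 inhibition in rapamycin-treated Tsc2-deficient cells prints, for
#' each GO-BP-style term, the counts behind the test: GeneRatio `k/n`
#' (annotated in foreground / foreground size) and BgRatio `K/N` (annotated in
#' universe / universe size), together with the reported p-value. Those counts
#' are bundled here as a plain-text fixture so the upper-tail hypergeometric
#' computation can be re-run desk-side against the printed values — the one
#' published computation whose full inputs are published with it.
#'
#' @return data.frame with columns `description`, `k`, `n`, `K`, `N`,
#'   `reported_pvalue` (40 rows).
#' @examples
#' rows <- reported_enrichment_rows()
#' hypergeometric_pvalue(rows$k[1], rows$n[1], rows$K[1], rows$N[1])
#' @export
reported_enrichment_rows <- function() {
  path <- system.file("extdata", "mir21_enrichment_reported.tsv",
                      package = "netora", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}
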
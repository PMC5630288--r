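#' Normalize a gene symbol
#'
#' Trims whitespace and upper-cases a raw identifier so that symbols from
#' heterogeneous sources (and mouse/human case conventions, e.g. `Pdcd4` vs
#' `PDCD4`) collapse to one namespace. Upper-casing is used as a deliberate,
#' documented approximation of mouse-to-human orthology by symbol; no real
#' ortholog mapping is attempted.
#'
#' Empty strings and the common placeholders `"-"`, `"NA"`, `"NULL"`, `"."`
#' are unusable identifiers and map to `NA_character_`, the invalid marker.
#'
#' @param raw character vector of raw identifiers.
#' @return character vector of the same length; invalid entries are `NA`.
#' @examples
#' normalize_symbol(c("Pdcd4", " pten ", "-", ""))
#' @export
normalize_symbol <- function(raw) {
  out <- toupper(trimws(as.character(raw)))
  out[is.na(out) | out %in% c("", "-", "NA", "NULL", ".")] <- NA_character_
  out
}

# Canonical unordered-pair key: endpoints sorted lexicographically.
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\t"), paste(b, a, sep = "\t"))
}
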
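#' Canonical amino-acid and dipeptide orderings
#'
#' All scorecards, composition vectors and property tables in this package
#' are aligned on a single canonical ordering: the 20 standard one-letter
#' amino-acid codes sorted alphabetically, and the 400 dipeptides sorted
#' lexicographically (AA, AC, ..., YW, YY). Serialized files always carry
#' explicit symbol labels, so the ordering is a convenience, not a file
#' format contract.
#'
#' @param granularity `"amino_acid"` (20 symbols) or `"dipeptide"`
#'   (400 symbols).
#' @return A character vector of symbols in canonical order.
#' @examples
#' head(canonical_symbols("amino_acid"))
#' canonical_symbols("dipeptide")[1:5]
#' @export
canonical_symbols <- function(granularity = c("amino_acid", "dipeptide")) {
  granularity <- match.arg(granularity)
  if (granularity == "amino_acid") AA_ALPHABET_20 else DIPEPTIDES_400
}

AA_ALPHABET_20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

DIPEPTIDES_400 <- as.vector(t(outer(AA_ALPHABET_20, AA_ALPHABET_20, paste0)))

#' @rdname canonical_symbols
#' @param symbol Character vector of symbols to look up.
#' @return `canonical_index()`: integer positions in the canonical ordering
#'   (NA for unknown symbols).
#' @export
canonical_index <- function(symbol,
                            granularity = c("amino_acid", "dipeptide")) {
  granularity <- match.arg(granularity)
  match(symbol, canonical_symbols(granularity))
}
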
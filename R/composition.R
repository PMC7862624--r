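#' Amino-acid composition (AAC)
#'
#' The 20-dimensional proportion vector of a peptide: entry i is the count
#' of the i-th amino acid divided by the sequence length, in canonical
#' alphabetical order.
#'
#' @param sequence A single peptide sequence (length >= 1).
#' @return Named numeric vector of length 20 summing to 1.
#' @examples
#' aac("AC")
#' @export
aac <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 1L) stop("Empty sequence.", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  counts <- tabulate(factor(chars, levels = AA_ALPHABET_20), nbins = 20L)
  names(counts) <- AA_ALPHABET_20
  counts / length(chars)
}

#' Dipeptide counts and composition (DPC)
#'
#' `dipeptide_counts()` counts the overlapping adjacent residue pairs of a
#' sequence (a sequence of length L has L - 1 pairs). `dpc()` normalizes
#' those counts by the number of counted pairs, giving the 400-dimensional
#' dipeptide composition.
#'
#' For concatenated N+C terminal regions the pair straddling the junction
#' (last N-segment residue followed by first C-segment residue) does not
#' occur in the original peptide; `exclude_positions` removes chosen pair
#' positions (1-based index of the pair's first residue) from the count
#' before normalization.
#'
#' @param sequence A single peptide sequence (length >= 2).
#' @param exclude_positions Integer positions of pairs to drop (used for
#'   NC-region junction exclusion); default none.
#' @return `dipeptide_counts()`: named integer vector of length 400;
#'   `dpc()`: named numeric vector of length 400 summing to 1.
#' @examples
#' dpc("ACA")[c("AC", "CA")]
#' sum(dipeptide_counts("KAKLF"))
#' @export
dipeptide_counts <- function(sequence, exclude_positions = integer(0)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 2L) {
    stop("Sequence must have at least 2 residues to form a dipeptide.",
         call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  pairs <- paste0(chars[-n], chars[-1L])
  if (length(exclude_positions)) {
    keep <- setdiff(seq_len(n - 1L), exclude_positions)
    pairs <- pairs[keep]
  }
  counts <- tabulate(factor(pairs, levels = DIPEPTIDES_400), nbins = 400L)
  names(counts) <- DIPEPTIDES_400
  counts
}

#' @rdname dipeptide_counts
#' @export
dpc <- function(sequence, exclude_positions = integer(0)) {
  counts <- dipeptide_counts(sequence, exclude_positions)
  total <- sum(counts)
  if (total == 0L) {
    stop("No dipeptide pairs left after exclusions.", call. = FALSE)
  }
  counts / total
}

#' Composition matrix for a peptide set on a region
#'
#' Region-slices every sequence and stacks the per-peptide composition
#' vectors (AAC for amino-acid regions, DPC for dipeptide regions) into an
#' n x 20 or n x 400 matrix with canonical column names. This is the
#' feature matrix the scorecard scoring function operates on.
#'
#' Peptides whose region slice is shorter than 2 residues under a dipeptide
#' granularity are unscorable: their row is all-`NA` and their index is
#' recorded in the `unscorable` attribute rather than being silently
#' dropped.
#'
#' @param peptides Peptide tibble (column `sequence`) or character vector.
#' @param region Region name or [region_spec()].
#' @param junction For NC regions: `"include"` (default) counts the pair
#'   straddling the N/C junction; `"exclude"` drops it.
#' @param weighting `"composition"` (default) rows are normalized
#'   proportions; `"count"` rows are raw counts (amino-acid granularity
#'   always uses proportions).
#' @return Numeric matrix, rows per peptide, with attribute `unscorable`.
#' @export
composition_matrix <- function(peptides, region,
                               junction = c("include", "exclude"),
                               weighting = c("composition", "count")) {
  junction <- match.arg(junction)
  weighting <- match.arg(weighting)
  region <- region_spec(region)
  seqs <- if (is.data.frame(peptides)) peptides$sequence else peptides
  sliced <- extract_region(seqs, region)

  if (region$granularity == "amino_acid") {
    mat <- t(vapply(sliced, aac, numeric(20L), USE.NAMES = FALSE))
    colnames(mat) <- AA_ALPHABET_20
    attr(mat, "unscorable") <- integer(0)
    return(mat)
  }

  excl <- vector("list", length(sliced))
  if (region$kind == "NC" && junction == "exclude") {
    jpos <- nc_junction_position(seqs, region)
    excl <- as.list(jpos)
  }
  ok <- nchar(sliced) >= 2L
  mat <- matrix(NA_real_, nrow = length(sliced), ncol = 400L,
                dimnames = list(NULL, DIPEPTIDES_400))
  for (i in which(ok)) {
    counts <- dipeptide_counts(sliced[i], excl[[i]] %||% integer(0))
    total <- sum(counts)
    if (total == 0L) {
      ok[i] <- FALSE
      next
    }
    mat[i, ] <- if (weighting == "composition") counts / total else counts
  }
  attr(mat, "unscorable") <- which(!ok)
  mat
}

#' Pooled class composition of a labeled peptide set
#'
#' Pools the region-sliced symbol counts of each class and normalizes by
#' the class total, giving the per-class composition vectors from which an
#' initial scorecard is derived: `nps_pos[i] = count_pos[i] / total_pos`
#' and likewise for the negative class.
#'
#' @inheritParams composition_matrix
#' @param peptides Labeled peptide tibble (`sequence`, `label`).
#' @return An `fscm_class_composition` object: named count vectors
#'   `counts_pos`/`counts_neg`, totals, and normalized vectors
#'   `nps_pos`/`nps_neg`.
#' @examples
#' set <- generate_peptides(synthetic_config(n_positive = 20, n_negative = 20))
#' cc <- class_composition(set, "DPS")
#' sum(cc$nps_pos)
#' @export
class_composition <- function(peptides, region,
                              junction = c("include", "exclude")) {
  junction <- match.arg(junction)
  region <- region_spec(region)
  stopifnot(all(c("sequence", "label") %in% names(peptides)))
  if (!all(c("positive", "negative") %in% peptides$label)) {
    stop("class_composition needs both positive and negative records.",
         call. = FALSE)
  }
  count_class <- function(df) {
    m <- composition_matrix(df, region, junction = junction,
                            weighting = "count")
    if (region$granularity == "amino_acid") {
      # amino-acid granularity pools residue counts, not proportions
      m <- m * nchar(extract_region(df$sequence, region))
    }
    keep <- setdiff(seq_len(nrow(m)), attr(m, "unscorable"))
    counts <- colSums(m[keep, , drop = FALSE])
    round(counts)
  }
  counts_pos <- count_class(peptides[peptides$label == "positive", ])
  counts_neg <- count_class(peptides[peptides$label == "negative", ])
  class_composition_from_counts(counts_pos, counts_neg,
                                region = region, junction = junction)
}

#' Build a class composition summary from explicit counts
#'
#' Lower-level constructor used by [class_composition()] and for worked
#' examples where pooled counts and class totals are given directly.
#'
#' @param counts_pos,counts_neg Named non-negative count vectors over the
#'   canonical symbols (missing symbols are taken as 0).
#' @param total_pos,total_neg Class totals; default the sum of the counts.
#'   Totals may exceed the counted sum when only a subset of symbols is
#'   supplied.
#' @param region Region spec recorded for provenance (optional).
#' @param junction Junction convention recorded for provenance.
#' @return An `fscm_class_composition` object.
#' @export
class_composition_from_counts <- function(counts_pos, counts_neg,
                                          total_pos = sum(counts_pos),
                                          total_neg = sum(counts_neg),
                                          region = NULL,
                                          junction = "include") {
  granularity <- if (length(counts_pos) == 20L ||
                     all(nchar(names(counts_pos)) == 1L)) {
    "amino_acid"
  } else {
    "dipeptide"
  }
  symbols <- canonical_symbols(granularity)
  expand <- function(x) {
    out <- stats::setNames(numeric(length(symbols)), symbols)
    if (is.null(names(x)) && length(x) == length(symbols)) {
      out[] <- x
    } else {
      stopifnot(!is.null(names(x)), all(names(x) %in% symbols))
      out[names(x)] <- x
    }
    out
  }
  counts_pos <- expand(counts_pos)
  counts_neg <- expand(counts_neg)
  if (total_pos <= 0 || total_neg <= 0) {
    stop("Each class must contribute at least one counted symbol.",
         call. = FALSE)
  }
  structure(
    list(
      granularity = granularity,
      region = if (!is.null(region)) region_spec(region),
      junction = junction,
      counts_pos = counts_pos,
      counts_neg = counts_neg,
      total_pos = total_pos,
      total_neg = total_neg,
      nps_pos = counts_pos / total_pos,
      nps_neg = counts_neg / total_neg
    ),
    class = "fscm_class_composition"
  )
}

#' @export
print.fscm_class_composition <- function(x, ...) {
  cat(sprintf(
    "<fscm_class_composition> %s%s: %d symbols, totals %s (+) / %s (-)\n",
    x$granularity,
    if (!is.null(x$region)) paste0(" on ", x$region$name) else "",
    length(x$counts_pos),
    format(x$total_pos), format(x$total_neg)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
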
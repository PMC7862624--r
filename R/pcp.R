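#' Pearson correlation between two 20-value residue scales
#'
#' Thin validated wrapper around the product-moment correlation used to
#' compare amino-acid propensity scores with physicochemical property
#' indices. Unlike [safe_pearson()]'s permissive behaviour inside the GA,
#' a constant input here is an error: a property with no variation carries
#' no correlation signal.
#'
#' @param x,y Numeric vectors of equal length (normally 20, one value per
#'   residue), no missing values.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) {
    stop("pearson() does not accept missing values.", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Correlation undefined for a constant vector.", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Read a physicochemical property table
#'
#' Reads a flat TSV of residue scales: columns `accession`, `description`
#' and the 20 canonical residue letters (A, C, D, ..., Y) in any column
#' order. Records containing any missing value are excluded, as indices
#' with not-applicable entries cannot be correlated against a complete
#' propensity vector; the number excluded is reported in a message.
#'
#' @param path Path to the property TSV.
#' @return A tibble of complete records with attribute `n_excluded`.
#' @examples
#' tab <- read_pcp_table(fscm_extdata("reference_pcp.tsv"))
#' tab$accession
#' @export
read_pcp_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         na = c("NA", "na", ""))
  required <- c("accession", "description", AA_ALPHABET_20)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("Property table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning("Property table is empty.", call. = FALSE)
    out <- tab[, required]
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  tab <- tab[, required]
  complete <- stats::complete.cases(tab[, AA_ALPHABET_20])
  if (any(!complete)) {
    message(sum(!complete), " propert",
            if (sum(!complete) == 1L) "y" else "ies",
            " excluded for missing residue values.")
  }
  out <- tab[complete, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!complete)
  out
}

#' Correlate amino-acid propensities with property scales
#'
#' Computes the Pearson correlation between a 20-residue propensity
#' scorecard and every physicochemical property record, ranks properties
#' by absolute correlation and flags those exceeding the selection cutoff
#' (strictly greater than 0.5 by default) as informative. A dipeptide
#' scorecard is first reduced to amino-acid propensities via
#' [aa_propensities()].
#'
#' @param card An `fscm_scorecard` (amino-acid, or dipeptide to be
#'   reduced).
#' @param pcp_table Property tibble from [read_pcp_table()] (or any tibble
#'   with `accession`, `description` and the 20 residue columns).
#' @param cutoff Absolute-correlation selection cutoff (default 0.5,
#'   strict inequality).
#' @return A tibble sorted by `abs(r)` descending: `accession`,
#'   `description`, `r`, `selected`, `rank`. Records whose correlation is
#'   undefined (constant scale) get `r = NA` and `selected = FALSE`.
#' @examples
#' pcp_correlations(reference_scorecard(), reference_pcp())
#' @export
pcp_correlations <- function(card, pcp_table, cutoff = 0.5) {
  stopifnot(inherits(card, "fscm_scorecard"))
  if (card$granularity == "dipeptide") {
    message("Reducing dipeptide scorecard to amino-acid propensities.")
    card <- aa_propensities(card)
  }
  ps <- card$scores[AA_ALPHABET_20]
  if (nrow(pcp_table) == 0L) {
    warning("No property records to correlate.", call. = FALSE)
    return(tibble::tibble(accession = character(), description = character(),
                          r = numeric(), selected = logical(),
                          rank = integer()))
  }
  r <- vapply(seq_len(nrow(pcp_table)), function(i) {
    vals <- as.numeric(pcp_table[i, AA_ALPHABET_20])
    tryCatch(pearson(ps, vals), error = function(e) NA_real_)
  }, numeric(1))
  out <- tibble::tibble(
    accession = pcp_table$accession,
    description = pcp_table$description,
    r = r,
    selected = !is.na(r) & abs(r) > cutoff
  )
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$r)))
  out$rank <- seq_len(nrow(out))
  out
}
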
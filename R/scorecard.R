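#' Initial propensity scores from class composition
#'
#' The raw propensity of a symbol is the difference between its normalized
#' composition in the positive and negative classes,
#' `nps_pos - nps_neg`: positive values mark symbols enriched in the
#' positive class. (With pooled counts of 280/450 in the positive class and
#' 40/200 in the negative class, a dipeptide's normalized compositions are
#' 0.622 and 0.2 and its raw propensity is 0.422.)
#'
#' @param summary An `fscm_class_composition` from [class_composition()].
#' @return Named numeric vector of raw propensity differences.
#' @export
initial_propensity <- function(summary) {
  stopifnot(inherits(summary, "fscm_class_composition"))
  summary$nps_pos - summary$nps_neg
}

#' Min-max normalization to the 0-1000 propensity scale
#'
#' Affine map `x -> 1000 * (x - min) / (max - min)`: the smallest raw score
#' becomes 0 and the largest 1000. A constant vector (no spread) maps to the
#' direction-neutral midpoint 500 for every entry rather than erroring, so
#' degenerate folds keep pipelines alive.
#'
#' @param raw Numeric vector of raw scores.
#' @return Numeric vector on the 0-1000 scale, names preserved.
#' @examples
#' normalize_0_1000(c(-0.5, 0, 0.5))
#' @export
normalize_0_1000 <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 1L)
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    out <- rep(500, length(raw))
    names(out) <- names(raw)
    return(out)
  }
  # divide before scaling so the maximum maps to exactly 1000
  (raw - rng[1]) / (rng[2] - rng[1]) * 1000
}

#' Construct a scorecard object
#'
#' A scorecard assigns every amino acid (20 entries) or dipeptide
#' (400 entries) a propensity score on the 0-1000 scale, carries the region
#' it was trained on and the decision threshold used to classify the
#' weighted-sum peptide score.
#'
#' @param scores Named numeric vector over the full canonical symbol set
#'   (20 or 400 entries).
#' @param region Region name or [region_spec()].
#' @param threshold Decision cutoff on the 0-1000 score scale (`NA` until
#'   fitted).
#' @param provenance `"initial"`, `"optimized"` or `"external"`.
#' @param metadata Optional named list (dataset name, seed, GA settings).
#' @return An object of class `fscm_scorecard`.
#' @export
new_scorecard <- function(scores, region, threshold = NA_real_,
                          provenance = c("initial", "optimized", "external"),
                          metadata = list()) {
  provenance <- match.arg(provenance)
  region <- region_spec(region)
  symbols <- canonical_symbols(region$granularity)
  if (is.null(names(scores))) {
    stopifnot(length(scores) == length(symbols))
    names(scores) <- symbols
  }
  if (!setequal(names(scores), symbols)) {
    missing <- setdiff(symbols, names(scores))
    extra <- setdiff(names(scores), symbols)
    stop("Scorecard symbols do not match the ", region$granularity,
         " symbol set.",
         if (length(missing)) paste0(" Missing: ",
                                     paste(utils::head(missing, 5),
                                           collapse = ", "), "."),
         if (length(extra)) paste0(" Unexpected: ",
                                   paste(utils::head(extra, 5),
                                         collapse = ", "), "."),
         call. = FALSE)
  }
  scores <- scores[symbols]
  stopifnot(all(is.finite(scores)))
  structure(
    list(scores = scores, region = region,
         granularity = region$granularity,
         threshold = threshold, provenance = provenance,
         metadata = metadata),
    class = "fscm_scorecard"
  )
}

#' Estimate an initial scorecard from labeled peptides
#'
#' Pools class compositions on the requested region, takes the
#' positive-minus-negative composition difference per symbol, min-max
#' scales it to 0-1000 and (optionally) fits the decision threshold on the
#' training scores. This is the statistically initialized scorecard that
#' genetic-algorithm refinement starts from.
#'
#' @inheritParams class_composition
#' @param fit_threshold Fit the accuracy-maximizing threshold on the
#'   training data (default `TRUE`).
#' @return An `fscm_scorecard` with provenance `"initial"`.
#' @examples
#' set <- generate_peptides(synthetic_config(n_positive = 30, n_negative = 30))
#' card <- initial_scorecard(set, "DPS")
#' card
#' @export
initial_scorecard <- function(peptides, region,
                              junction = c("include", "exclude"),
                              fit_threshold = TRUE) {
  junction <- match.arg(junction)
  region <- region_spec(region)
  cc <- class_composition(peptides, region, junction = junction)
  scores <- normalize_0_1000(initial_propensity(cc))
  card <- new_scorecard(scores, region, provenance = "initial",
                        metadata = list(junction = junction,
                                        n_train = nrow(peptides)))
  if (fit_threshold) {
    sc <- score_peptides(peptides, card, junction = junction)
    card$threshold <- select_threshold(sc$score, peptides$label)
  }
  card
}

#' Reduce a dipeptide scorecard to amino-acid propensities
#'
#' The propensity of residue r is the mean of the 40 dipeptide scores
#' containing r: the 20 pairs rX plus the 20 pairs Xr, with the doubled
#' pair rr contributing twice. This is how whole-residue propensities (and
#' hence physicochemical-property correlations) are derived from a
#' dipeptide card.
#'
#' @param card An `fscm_scorecard` with dipeptide granularity.
#' @return An `fscm_scorecard` with amino-acid granularity on the APS
#'   region; threshold is not carried over (it belongs to the dipeptide
#'   feature space).
#' @export
aa_propensities <- function(card) {
  stopifnot(inherits(card, "fscm_scorecard"))
  if (card$granularity != "dipeptide") {
    stop("aa_propensities expects a dipeptide scorecard.", call. = FALSE)
  }
  ps <- card$scores
  aa_scores <- vapply(AA_ALPHABET_20, function(r) {
    lead <- ps[paste0(r, AA_ALPHABET_20)]
    trail <- ps[paste0(AA_ALPHABET_20, r)]
    (sum(lead) + sum(trail)) / 40
  }, numeric(1))
  new_scorecard(aa_scores, "APS", provenance = card$provenance,
                metadata = c(card$metadata,
                             list(reduced_from = card$region$name)))
}

#' @export
print.fscm_scorecard <- function(x, ...) {
  cat(sprintf(
    "<fscm_scorecard> %s (%s, %d symbols), provenance %s\n",
    x$region$name, gsub("_", "-", x$granularity), length(x$scores),
    x$provenance))
  cat(sprintf("  score range [%.2f, %.2f], threshold %s\n",
              min(x$scores), max(x$scores),
              if (is.na(x$threshold)) "unset" else
                sprintf("%.2f", x$threshold)))
  top <- sort(x$scores, decreasing = TRUE)[1:5]
  cat("  top symbols:",
      paste(sprintf("%s=%.1f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a scorecard into a symbol/score tibble
#'
#' @param x An `fscm_scorecard`.
#' @param ... Unused.
#' @return A tibble with columns `symbol`, `score`, `rank` (1 = highest
#'   score).
#' @export
tidy.fscm_scorecard <- function(x, ...) {
  tibble::tibble(
    symbol = names(x$scores),
    score = unname(x$scores),
    rank = rank(-x$scores, ties.method = "min")
  )
}

#' One-row summary of a scorecard
#'
#' @inheritParams tidy.fscm_scorecard
#' @return A one-row tibble: region, granularity, n_symbols, threshold,
#'   provenance, min/max/median score.
#' @export
glance.fscm_scorecard <- function(x, ...) {
  tibble::tibble(
    region = x$region$name,
    granularity = x$granularity,
    n_symbols = length(x$scores),
    threshold = x$threshold,
    provenance = x$provenance,
    min_score = min(x$scores),
    median_score = stats::median(x$scores),
    max_score = max(x$scores)
  )
}

#' Read and write scorecard files
#'
#' Scorecards are stored as headered TSV (`symbol`, `score`) preceded by a
#' commented metadata block (`# key: value` lines) carrying region,
#' threshold, provenance and any extra metadata. Scores round-trip at full
#' precision.
#'
#' @param card An `fscm_scorecard`.
#' @param path File path.
#' @return `write_scorecard()`: `path` invisibly; `read_scorecard()`: an
#'   `fscm_scorecard`.
#' @export
write_scorecard <- function(card, path) {
  stopifnot(inherits(card, "fscm_scorecard"))
  meta <- c(
    region = card$region$name,
    granularity = card$granularity,
    threshold = formatC(card$threshold, digits = 17, format = "g"),
    provenance = card$provenance
  )
  extra <- vapply(card$metadata, function(v) paste(format(v), collapse = ","),
                  character(1))
  meta <- c(meta, extra)
  header <- sprintf("# %s: %s", names(meta), meta)
  body <- sprintf("%s\t%s", names(card$scores),
                  formatC(card$scores, digits = 17, format = "g"))
  writeLines(c(header, "symbol\tscore", body), path)
  invisible(path)
}

#' @rdname write_scorecard
#' @export
read_scorecard <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- stringr::str_match(ln, "^#\\s*([^:]+):\\s*(.*)$")
    if (!is.na(kv[1, 1])) meta[[trimws(kv[1, 2])]] <- trimws(kv[1, 3])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  # na.strings must stay empty: "NA" is the Asn-Ala dipeptide symbol
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE,
                           na.strings = character(0),
                           colClasses = c("character", "numeric"))
  if (!all(c("symbol", "score") %in% names(tab))) {
    stop("Scorecard file lacks symbol/score columns: ", path, call. = FALSE)
  }
  if (anyDuplicated(tab$symbol)) {
    stop("Duplicate symbol in scorecard file: ",
         tab$symbol[duplicated(tab$symbol)][1], call. = FALSE)
  }
  region <- meta$region %||% stop("Scorecard file lacks a region: ", path,
                                  call. = FALSE)
  scores <- stats::setNames(as.numeric(tab$score), tab$symbol)
  threshold <- suppressWarnings(as.numeric(meta$threshold %||% NA))
  prov <- meta$provenance %||% "external"
  if (!prov %in% c("initial", "optimized", "external")) prov <- "external"
  keep <- setdiff(names(meta),
                  c("region", "granularity", "threshold", "provenance"))
  new_scorecard(scores, region, threshold = threshold, provenance = prov,
                metadata = meta[keep])
}
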
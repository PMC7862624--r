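#' Synthetic peptide dataset configuration
#'
#' Describes a labeled synthetic benchmark with dipeptide-level planted
#' signal. Negatives are drawn residue-by-residue from the background
#' distribution; positives come from a first-order Markov chain whose
#' transition weight into residue b from residue a is multiplied by
#' `effect_size` when the pair ab is enriched (divided when depleted).
#' Because the unit of signal is the adjacent residue pair, recovery tests
#' on these data probe the dipeptide scorecard machinery directly.
#'
#' Defaults emulate a modest two-class peptide benchmark: 200 peptides per
#' class of length 10-30 over a uniform residue background, with the three
#' dipeptides KK, LW and GH planted at five-fold enrichment in positives.
#'
#' @param n_positive,n_negative Peptides per class (defaults 200 each).
#' @param length_range Inclusive (min, max) peptide lengths, min >= 2
#'   (default c(10, 30)).
#' @param background Named vector of 20 residue probabilities summing to 1
#'   (default uniform).
#' @param enriched Character vector of dipeptides enriched in positives
#'   (default KK, LW, GH).
#' @param depleted Character vector of dipeptides depleted in positives
#'   (default none).
#' @param effect_size Multiplicative enrichment factor > 0 (default 5;
#'   1 plants no signal, making the classes exchangeable).
#' @param seed Integer master seed (default 7).
#' @return A list of class `fscm_synthetic_config`.
#' @export
synthetic_config <- function(n_positive = 200L, n_negative = 200L,
                             length_range = c(10L, 30L),
                             background = NULL,
                             enriched = c("KK", "LW", "GH"),
                             depleted = character(0),
                             effect_size = 5, seed = 7L) {
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET_20)
  }
  stopifnot(length(background) == 20L,
            abs(sum(background) - 1) < 1e-8,
            all(background >= 0))
  if (is.null(names(background))) names(background) <- AA_ALPHABET_20
  if (length_range[1] < 2L || length_range[2] < length_range[1]) {
    stop("length_range must satisfy 2 <= min <= max.", call. = FALSE)
  }
  if (effect_size <= 0) stop("effect_size must be positive.", call. = FALSE)
  bad <- setdiff(c(enriched, depleted), DIPEPTIDES_400)
  if (length(bad)) {
    stop("Not dipeptides: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_positive = as.integer(n_positive),
         n_negative = as.integer(n_negative),
         length_range = as.integer(length_range),
         background = background[AA_ALPHABET_20],
         enriched = enriched, depleted = depleted,
         effect_size = effect_size, seed = as.integer(seed)),
    class = "fscm_synthetic_config"
  )
}

#' Generate a labeled synthetic peptide set
#'
#' See [synthetic_config()] for the generative model. Each sequence draws
#' from its own counter-derived sub-seed, so a dataset is reproducible for
#' a fixed config and stable under regeneration of any subset.
#'
#' @param config An [synthetic_config()].
#' @return A labeled peptide tibble (`id`, `sequence`, `label`).
#' @examples
#' set <- generate_peptides(synthetic_config(n_positive = 5, n_negative = 5))
#' set
#' @export
generate_peptides <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "fscm_synthetic_config"))
  bg <- config$background
  if (all(bg == 0)) stop("Degenerate background.", call. = FALSE)

  # 20 x 20 transition matrix: row a gives the distribution of the next
  # residue following a; positives get tilted rows, negatives use bg rows
  trans <- matrix(rep(bg, each = 20L), nrow = 20L,
                  dimnames = list(AA_ALPHABET_20, AA_ALPHABET_20))
  for (d in config$enriched) {
    a <- substr(d, 1, 1); b <- substr(d, 2, 2)
    trans[a, b] <- trans[a, b] * config$effect_size
  }
  for (d in config$depleted) {
    a <- substr(d, 1, 1); b <- substr(d, 2, 2)
    trans[a, b] <- trans[a, b] / config$effect_size
  }
  if (any(rowSums(trans) == 0)) {
    stop("Degenerate transition row; no continuation possible.",
         call. = FALSE)
  }
  trans <- trans / rowSums(trans)

  draw_seq <- function(sub_seed, markov) {
    withr::with_seed(sub_seed, {
      len <- sample(seq(config$length_range[1], config$length_range[2]), 1L)
      s <- character(len)
      s[1] <- sample(AA_ALPHABET_20, 1L, prob = bg)
      for (i in seq_len(len - 1L)) {
        p <- if (markov) trans[s[i], ] else bg
        s[i + 1L] <- sample(AA_ALPHABET_20, 1L, prob = p)
      }
      paste(s, collapse = "")
    })
  }

  # counter-derived sub-seeds, hashed so different master seeds give
  # non-overlapping streams while each (seed, class, counter) stays fixed
  sub_seed <- function(k, offset) {
    as.integer((as.double(config$seed) * 1103515245 + k * 12345 + offset) %%
                 2147483647)
  }
  pos <- vapply(seq_len(config$n_positive), function(k) {
    draw_seq(sub_seed(k, 0), markov = TRUE)
  }, character(1))
  neg <- vapply(seq_len(config$n_negative), function(k) {
    draw_seq(sub_seed(k, 1073741824), markov = FALSE)
  }, character(1))
  tibble::tibble(
    id = c(sprintf("pos_%04d", seq_along(pos)),
           sprintf("neg_%04d", seq_along(neg))),
    sequence = c(pos, neg),
    label = rep(c("positive", "negative"), c(length(pos), length(neg)))
  )
}

#' Path to a packaged fixture file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path to the installed fixture.
#' @export
fscm_extdata <- function(file) {
  path <- system.file("extdata", file, package = "fscm", mustWork = FALSE)
  if (!nzchar(path)) stop("No packaged file '", file, "'.", call. = FALSE)
  path
}

#' Packaged amino-acid propensity reference card
#'
#' The published 20-residue propensity column (derived from a
#' whole-sequence dipeptide scorecard on the anticancer-peptide main
#' benchmark; Tyr highest at 355.55, Gln lowest at 198.45), stored at its
#' printed 2-decimal precision. Used to exercise the property-correlation
#' workflow offline.
#'
#' @return An `fscm_scorecard` with amino-acid granularity, provenance
#'   `"external"` and no threshold.
#' @examples
#' reference_scorecard()$scores[c("Y", "Q")]
#' @export
reference_scorecard <- function() {
  tab <- utils::read.delim(fscm_extdata("reference_propensity.tsv"),
                           stringsAsFactors = FALSE)
  new_scorecard(stats::setNames(tab$score, tab$symbol), "APS",
                provenance = "external",
                metadata = list(source = "published reference card"))
}

#' Packaged physicochemical property records
#'
#' The three published informative residue scales: MITS020101
#' (amphiphilicity index), QIAN880113 (alpha-helix weight at window
#' position 6) and JOND750101 (hydrophobicity), at printed precision.
#'
#' @return A property tibble as returned by [read_pcp_table()].
#' @export
reference_pcp <- function() {
  read_pcp_table(fscm_extdata("reference_pcp.tsv"))
}

#' @rdname reference_pcp
#' @return `reference_correlations_printed()`: the correlations printed
#'   alongside the reference card, for provenance. Note that the JOND750101
#'   entry (0.541) does not agree with recomputation from the printed
#'   columns (0.451); the other two do.
#' @export
reference_correlations_printed <- function() {
  c(MITS020101 = 0.577, QIAN880113 = 0.569, JOND750101 = 0.541)
}

#' Worked-example class composition
#'
#' The didactic pooled-count example used throughout the scorecard
#' documentation: dipeptide KK counted 280 times among 450 positive-class
#' dipeptides and 40 times among 200 negative-class dipeptides, giving
#' normalized compositions 0.622 and 0.2 and a raw propensity difference
#' of 0.422.
#'
#' @return An `fscm_class_composition` over the 400 dipeptides with only
#'   the KK counts filled in.
#' @examples
#' cc <- worked_example_composition()
#' round(cc$nps_pos["KK"], 3)
#' @export
worked_example_composition <- function() {
  class_composition_from_counts(
    counts_pos = c(KK = 280), counts_neg = c(KK = 40),
    total_pos = 450, total_neg = 200
  )
}
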
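#' Region specifications for terminal-window features
#'
#' A region spec names the part of each peptide a scorecard is built on and
#' the feature granularity used there. Eleven combinations are supported,
#' matching the eleven scorecard flavours: whole-sequence amino-acid
#' composition (`APS`), whole-sequence dipeptide composition (`DPS`), and
#' dipeptide composition on the first/last 5, 10 or 15 residues or their
#' concatenation (`N5`, `C5`, `N5C5`, `N10`, `C10`, `N10C10`, `N15`, `C15`,
#' `N15C15`).
#'
#' @param name Region name. Both plain (`"C15"`) and propensity-score
#'   suffixed (`"C15PS"`) spellings are accepted, case-insensitively.
#' @return An object of class `fscm_region` with fields `name`, `kind`
#'   (`"FULL"`, `"N"`, `"C"`, `"NC"`), `window` (5, 10 or 15; `NA` for
#'   FULL regions) and `granularity`.
#' @examples
#' region_spec("C15")
#' region_spec("APS")
#' @export
region_spec <- function(name) {
  if (inherits(name, "fscm_region")) {
    return(name)
  }
  stopifnot(is.character(name), length(name) == 1L)
  key <- sub("PS$", "", toupper(name))
  # stripping the PS suffix reduces "APS"/"DPS" to bare letters
  if (key == "A") key <- "APS"
  if (key == "D") key <- "DPS"
  table <- region_table()
  hit <- table[table$key == key, ]
  if (nrow(hit) != 1L) {
    stop("Unknown region '", name, "'. Valid regions: ",
         paste(region_names(), collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = hit$key, kind = hit$kind, window = hit$window,
         granularity = hit$granularity),
    class = "fscm_region"
  )
}

region_table <- function() {
  data.frame(
    key = c("APS", "DPS", "N5", "C5", "N5C5", "N10", "C10", "N10C10",
            "N15", "C15", "N15C15"),
    kind = c("FULL", "FULL", "N", "C", "NC", "N", "C", "NC",
             "N", "C", "NC"),
    window = c(NA, NA, 5, 5, 5, 10, 10, 10, 15, 15, 15),
    granularity = c("amino_acid", rep("dipeptide", 10)),
    stringsAsFactors = FALSE
  )
}

#' @rdname region_spec
#' @return `region_names()`: the 11 valid region names.
#' @export
region_names <- function() region_table()$key

#' @export
print.fscm_region <- function(x, ...) {
  win <- if (is.na(x$window)) "whole sequence" else {
    switch(x$kind,
           N = sprintf("first %d residues", x$window),
           C = sprintf("last %d residues", x$window),
           NC = sprintf("first %d + last %d residues", x$window, x$window))
  }
  cat(sprintf("<fscm_region> %s: %s, %s features\n",
              x$name, win, gsub("_", "-", x$granularity)))
  invisible(x)
}

#' Slice a peptide sequence to a region
#'
#' Extracts the sub-sequence a region spec refers to. Sequences shorter than
#' the terminal window are used whole (truncation): the benchmark datasets
#' contain peptides shorter than 15 residues and no minimum length is
#' imposed beyond the two residues needed for a dipeptide.
#'
#' @param sequence Character vector of peptide sequences.
#' @param region A region name or [region_spec()] object.
#' @return Character vector of region-sliced sequences. For `NC` regions the
#'   result is the N-segment followed by the C-segment; segments may overlap
#'   in the original peptide when it is shorter than twice the window.
#' @examples
#' extract_region("ACDEFGHIKL", "N5")
#' extract_region("ACDEFGHIKL", "N5C5")
#' @export
extract_region <- function(sequence, region) {
  region <- region_spec(region)
  if (region$kind == "FULL") {
    return(sequence)
  }
  w <- region$window
  len <- nchar(sequence)
  n_seg <- substr(sequence, 1L, pmin(w, len))
  c_seg <- substr(sequence, pmax(1L, len - w + 1L), len)
  switch(region$kind,
         N = n_seg,
         C = c_seg,
         NC = paste0(n_seg, c_seg))
}

# Length of the N-segment for each sequence under an NC region; used to
# locate the junction dipeptide position when it is to be excluded.
nc_junction_position <- function(sequence, region) {
  region <- region_spec(region)
  stopifnot(region$kind == "NC")
  pmin(region$window, nchar(sequence))
}
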
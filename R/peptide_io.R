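#' Read a labeled peptide set from FASTA
#'
#' Reads a FASTA file into a peptide tibble, uppercasing sequences and
#' applying a single class label to every record. The id is the header text
#' up to the first whitespace; wrapped sequence lines are joined.
#'
#' Records containing residues outside the 20 standard one-letter codes are
#' handled per `invalid`: `"skip"` (the default for dataset loading) drops
#' them with a warning naming the count, `"reject"` raises an error naming
#' the first offending record and position. Records shorter than two
#' residues carry no dipeptide and are treated the same way.
#'
#' @param path Path to a FASTA file.
#' @param label Optional class label applied to all records, usually
#'   `"positive"` or `"negative"`; `NA` leaves records unlabeled (e.g. for
#'   prediction input).
#' @param invalid Policy for sequences with non-standard residues or
#'   length < 2: `"skip"` or `"reject"`.
#' @return A tibble with columns `id`, `sequence`, `label`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "KAKLF", ">p2 some description", "alwktllkk"), fa)
#' read_fasta(fa, label = "positive")
#' @export
read_fasta <- function(path, label = NA_character_,
                       invalid = c("skip", "reject")) {
  invalid <- match.arg(invalid)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("Empty FASTA file (no records): ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  df <- tibble::tibble(
    id = ids,
    sequence = unname(toupper(as.character(set))),
    label = rep(as.character(label), length(set))
  )
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    stop("Duplicate FASTA ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  validate_peptides(df, invalid = invalid)
}

#' Write peptides to FASTA
#'
#' @param peptides A peptide tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path) {
  stopifnot(all(c("id", "sequence") %in% names(peptides)))
  set <- Biostrings::BStringSet(peptides$sequence)
  names(set) <- peptides$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Validate peptide sequences against the 20-letter alphabet
#'
#' @param peptides A tibble with columns `id` and `sequence` (a `label`
#'   column is carried through if present).
#' @param invalid `"reject"` errors on the first bad record, naming the
#'   offending position; `"skip"` drops bad records with a warning.
#' @return The validated tibble (rows possibly dropped under `"skip"`), with
#'   attribute `n_skipped` recording how many records were removed.
#' @export
validate_peptides <- function(peptides, invalid = c("reject", "skip")) {
  invalid <- match.arg(invalid)
  stopifnot(all(c("id", "sequence") %in% names(peptides)))
  seqs <- toupper(peptides$sequence)
  bad_pos <- stringr::str_locate(seqs, "[^ACDEFGHIKLMNPQRSTVWY]")[, 1]
  too_short <- nchar(seqs) < 2L
  bad <- !is.na(bad_pos) | too_short
  if (any(bad) && invalid == "reject") {
    i <- which(bad)[1L]
    if (too_short[i]) {
      stop("Sequence '", peptides$id[i], "' is shorter than 2 residues; ",
           "no dipeptide can be formed.", call. = FALSE)
    }
    stop("Sequence '", peptides$id[i], "' contains non-standard residue '",
         substr(seqs[i], bad_pos[i], bad_pos[i]), "' at position ",
         bad_pos[i], ".", call. = FALSE)
  }
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped (non-standard residues or ",
            "length < 2).", call. = FALSE)
  }
  out <- peptides[!bad, , drop = FALSE]
  out$sequence <- seqs[!bad]
  out <- tibble::as_tibble(out)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Combine positive and negative peptide files into one labeled set
#'
#' Convenience wrapper mirroring the two-FASTA benchmark layout.
#'
#' @param positive_path,negative_path FASTA paths for the two classes.
#' @param invalid Passed to [read_fasta()].
#' @return A labeled peptide tibble; ids are prefixed `pos_`/`neg_` on
#'   collision between the two files.
#' @export
read_labeled_fasta <- function(positive_path, negative_path,
                               invalid = c("skip", "reject")) {
  invalid <- match.arg(invalid)
  pos <- read_fasta(positive_path, label = "positive", invalid = invalid)
  neg <- read_fasta(negative_path, label = "negative", invalid = invalid)
  if (any(pos$id %in% neg$id)) {
    pos$id <- paste0("pos_", pos$id)
    neg$id <- paste0("neg_", neg$id)
  }
  dplyr::bind_rows(pos, neg)
}

#' Stratified train/test split
#'
#' Splits a labeled peptide set into training and test partitions,
#' stratified by label, with exact per-class counts
#' (`round(train_fraction * n_class)`) and a deterministic seeded shuffle.
#'
#' @param peptides Labeled peptide tibble (column `label` with two classes).
#' @param train_fraction Proportion assigned to training, in (0, 1).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return A list with elements `train` and `test`, both tibbles; together
#'   they partition the input exactly.
#' @examples
#' set <- generate_peptides(synthetic_config(n_positive = 20, n_negative = 20))
#' sp <- split_peptides(set, 0.8, seed = 1)
#' nrow(sp$train); nrow(sp$test)
#' @export
split_peptides <- function(peptides, train_fraction = 0.8, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1.", call. = FALSE)
  }
  stopifnot("label" %in% names(peptides))
  counts <- table(peptides$label)
  if (any(counts < 2L)) {
    stop("Each label class needs at least 2 records for a stratified split.",
         call. = FALSE)
  }
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(peptides$label == cl)
      n_train <- round(train_fraction * length(idx))
      n_train <- max(1L, min(length(idx) - 1L, n_train))
      sample(idx, n_train)
    }), use.names = FALSE)
  })
  list(
    train = peptides[sort(train_idx), , drop = FALSE],
    test = peptides[setdiff(seq_len(nrow(peptides)), train_idx), ,
                    drop = FALSE]
  )
}
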
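# Independent oracles and tiny fixture builders shared across tests.

# Brute-force Mann-Whitney AUC: enumerate every (positive, negative) pair,
# full credit when the positive scores higher, half credit on ties.
auc_bruteforce <- function(scores, truth) {
  pos <- scores[truth == "positive"]
  neg <- scores[truth == "negative"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Closed-form MCC evaluated directly from counts.
mcc_oracle <- function(tp, tn, fp, fn) {
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
}

# Pearson correlation from first principles (covariance over sd product).
pearson_oracle <- function(x, y) {
  n <- length(x)
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cov_xy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
              sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# Tiny labeled peptide tibble from raw sequences.
peptide_tbl <- function(pos = character(0), neg = character(0)) {
  tibble::tibble(
    id = c(sprintf("p%d", seq_along(pos)), sprintf("n%d", seq_along(neg))),
    sequence = c(pos, neg),
    label = rep(c("positive", "negative"), c(length(pos), length(neg)))
  )
}

# Write a temporary FASTA and return its path.
write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A perfectly separable two-class set: positives are lysine-rich,
# negatives glycine-rich, so a KK-heavy scorecard splits them cleanly.
separable_set <- function(n_per_class = 10) {
  pos <- replicate(n_per_class, paste(
    sample(c("K", "L", "A"), 12, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    collapse = ""))
  neg <- replicate(n_per_class, paste(
    sample(c("G", "S", "T"), 12, replace = TRUE), collapse = ""))
  peptide_tbl(pos, neg)
}
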
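#' Score peptides with a scorecard
#'
#' The peptide score is the composition-weighted sum of propensity scores,
#' `S(P) = sum_i x_i * PS_i`, where `x_i` is the normalized composition of
#' symbol i on the card's region. Because the weights sum to 1, S(P) is a
#' weighted mean of card scores and always lies within the card's score
#' range on the 0-1000 scale, independent of peptide length. Setting
#' `weighting = "count"` replaces proportions with raw occurrence counts,
#' in which case scores grow with length.
#'
#' @param peptides Peptide tibble (`id`, `sequence`; `label` carried
#'   through) or character vector of sequences.
#' @param card An `fscm_scorecard`.
#' @param junction NC-region junction convention, see
#'   [composition_matrix()].
#' @param weighting `"composition"` (default) or `"count"`.
#' @return A tibble with columns `id`, `sequence`, `score`, `predicted`
#'   (from the card threshold; `NA` if the threshold is unset) and
#'   `unscorable` (region slice too short to form a dipeptide).
#' @examples
#' set <- generate_peptides(synthetic_config(n_positive = 20, n_negative = 20))
#' card <- initial_scorecard(set, "DPS")
#' score_peptides(set, card)
#' @export
score_peptides <- function(peptides, card,
                           junction = c("include", "exclude"),
                           weighting = c("composition", "count")) {
  junction <- match.arg(junction)
  weighting <- match.arg(weighting)
  stopifnot(inherits(card, "fscm_scorecard"))
  if (!is.data.frame(peptides)) {
    peptides <- tibble::tibble(
      id = paste0("seq", seq_along(peptides)), sequence = peptides)
  }
  mat <- composition_matrix(peptides, card$region, junction = junction,
                            weighting = weighting)
  scores <- as.vector(mat %*% card$scores)
  unscorable <- seq_len(nrow(peptides)) %in% attr(mat, "unscorable")
  out <- tibble::tibble(
    id = peptides$id,
    sequence = peptides$sequence,
    score = scores,
    predicted = classify(scores, card$threshold),
    unscorable = unscorable
  )
  if ("label" %in% names(peptides)) out$label <- peptides$label
  out
}

#' Classify scores against a threshold
#'
#' A peptide is called positive if and only if its score strictly exceeds
#' the threshold; a score equal to the threshold is negative.
#'
#' @param score Numeric scores.
#' @param threshold Decision cutoff (`NA` gives `NA` predictions).
#' @return Character vector of `"positive"`/`"negative"`.
#' @export
classify <- function(score, threshold) {
  ifelse(is.na(score) | is.na(threshold), NA_character_,
         ifelse(score > threshold, "positive", "negative"))
}

#' Accuracy-maximizing decision threshold
#'
#' Scans the midpoints of adjacent sorted unique training scores — plus a
#' cutoff below the minimum and the maximum itself, which realize the
#' all-positive and all-negative rules — and returns the cutoff with the
#' highest training accuracy under the strict `score > threshold` rule;
#' ties are broken toward the lower cutoff, favouring sensitivity. The
#' boundary candidates guarantee the selected cutoff never does worse than
#' the majority rule.
#'
#' @param scores Numeric training scores.
#' @param labels Matching `"positive"`/`"negative"` labels.
#' @return A single numeric cutoff.
#' @examples
#' select_threshold(c(900, 800, 100, 200),
#'                  c("positive", "positive", "negative", "negative"))
#' @export
select_threshold <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- labels[keep]
  if (!all(c("positive", "negative") %in% labels)) {
    stop("select_threshold needs scores from both classes.", call. = FALSE)
  }
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warning("All scores identical; returning that value as threshold.",
            call. = FALSE)
    return(u)
  }
  # midpoints of adjacent unique scores, plus one cutoff below the minimum
  # (predict everything positive) and the maximum itself (predict everything
  # negative, since classification is strict) so the selected threshold can
  # never do worse than the majority rule on adversarial score patterns
  candidates <- c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2, u[length(u)])
  truth_pos <- labels == "positive"
  acc <- vapply(candidates, function(th) {
    mean((scores > th) == truth_pos)
  }, numeric(1))
  candidates[which.max(acc)] # which.max takes the first (lowest) maximizer
}

#' Confusion-matrix metrics
#'
#' Computes the confusion counts and the four threshold-dependent metrics:
#' accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A zero MCC
#' denominator returns 0 with a warning.
#'
#' @param truth,predicted Equal-length `"positive"`/`"negative"` vectors.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `ac`, `sn`, `sp`,
#'   `mcc`.
#' @export
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length.", call. = FALSE)
  }
  if (length(truth) == 0L) stop("Empty input.", call. = FALSE)
  tp <- sum(truth == "positive" & predicted == "positive")
  tn <- sum(truth == "negative" & predicted == "negative")
  fp <- sum(truth == "negative" & predicted == "positive")
  fn <- sum(truth == "positive" & predicted == "negative")
  n <- tp + tn + fp + fn
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) {
    warning("MCC denominator is zero; returning 0.", call. = FALSE)
    0
  } else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  }
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    ac = (tp + tn) / n,
    sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = mcc
  )
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney statistic: the fraction of
#' (positive, negative) score pairs where the positive scores higher, ties
#' counting one half. The ROC curve is traced by sweeping the threshold
#' through the observed scores in descending order; its trapezoidal area
#' equals the Mann-Whitney AUC.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param truth Matching `"positive"`/`"negative"` labels.
#' @return An object of class `fscm_roc`: list with `auc` and `points`
#'   (tibble of `threshold`, `fpr`, `tpr`).
#' @examples
#' roc_auc(c(3, 4, 1, 2), c("positive", "positive", "negative", "negative"))$auc
#' @export
roc_auc <- function(scores, truth) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  truth <- truth[keep]
  n_pos <- sum(truth == "positive")
  n_neg <- sum(truth == "negative")
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc needs scores from both classes.", call. = FALSE)
  }
  r <- rank(scores) # midranks give the tie-corrected Mann-Whitney statistic
  auc <- (sum(r[truth == "positive"]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  pos_sorted <- truth[ord] == "positive"
  # collapse tied scores to a single sweep point
  last_of_tie <- c(s_sorted[-length(s_sorted)] != s_sorted[-1L], TRUE)
  tpr <- cumsum(pos_sorted)[last_of_tie] / n_pos
  fpr <- cumsum(!pos_sorted)[last_of_tie] / n_neg
  points <- tibble::tibble(
    threshold = c(Inf, s_sorted[last_of_tie]),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  structure(list(auc = auc, points = points), class = "fscm_roc")
}

#' @export
print.fscm_roc <- function(x, ...) {
  cat(sprintf("<fscm_roc> AUC = %.4f (%d sweep points)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

# trapezoidal area under the swept curve; agrees with the Mann-Whitney AUC
roc_trapezoid_area <- function(roc) {
  p <- roc$points
  sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
}

#' Evaluate a scorecard on a labeled peptide set
#'
#' Scores every peptide, classifies against the card threshold and returns
#' the full metric suite (confusion counts, Ac, Sn, Sp, MCC, AUC and ROC
#' points). Unscorable peptides (region slice shorter than a dipeptide) are
#' excluded from the metrics and counted in `n_unscorable`.
#'
#' @inheritParams score_peptides
#' @param peptides Labeled peptide tibble.
#' @return An object of class `fscm_eval`: `metrics` (one-row tibble in
#'   table order: threshold, ac, sn, sp, mcc, auc), `roc` (an `fscm_roc`),
#'   `predictions` (per-peptide tibble), `n_unscorable`.
#' @export
evaluate_scorecard <- function(peptides, card,
                               junction = c("include", "exclude"),
                               weighting = c("composition", "count")) {
  junction <- match.arg(junction)
  weighting <- match.arg(weighting)
  if (is.na(card$threshold)) {
    stop("Scorecard has no threshold; fit one with select_threshold().",
         call. = FALSE)
  }
  preds <- score_peptides(peptides, card, junction = junction,
                          weighting = weighting)
  ok <- !preds$unscorable
  cm <- confusion_metrics(preds$label[ok], preds$predicted[ok])
  roc <- roc_auc(preds$score[ok], preds$label[ok])
  metrics <- tibble::tibble(
    threshold = card$threshold,
    ac = cm$ac, sn = cm$sn, sp = cm$sp, mcc = cm$mcc,
    auc = roc$auc,
    tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn
  )
  structure(
    list(metrics = metrics, roc = roc, predictions = preds,
         n_unscorable = sum(!ok), region = card$region$name),
    class = "fscm_eval"
  )
}

#' @export
print.fscm_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<fscm_eval> %s on %d peptides%s\n", x$region,
              nrow(x$predictions),
              if (x$n_unscorable)
                sprintf(" (%d unscorable)", x$n_unscorable) else ""))
  cat(sprintf(
    "  threshold %.2f | Ac %.3f  Sn %.3f  Sp %.3f  MCC %.3f  AUC %.3f\n",
    m$threshold, m$ac, m$sn, m$sp, m$mcc, m$auc))
  invisible(x)
}

#' @export
tidy.fscm_eval <- function(x, ...) x$predictions

#' @export
glance.fscm_eval <- function(x, ...) x$metrics

#' Stratified cross-validated AUC of fixed scorecard scores
#'
#' Partitions the peptides into stratified folds, scores each fold's
#' peptides with the fixed score vector and averages the per-fold AUCs.
#' The scores are global (nothing is refit per fold); cross-validation
#' here assesses ranking stability across subsamples. Folds missing a
#' class are skipped with a warning.
#'
#' @param scores Named score vector over the region's symbol set (or an
#'   `fscm_scorecard`).
#' @param peptides Labeled peptide tibble.
#' @param region Region name or spec (taken from the card if one is given).
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @param junction NC junction convention.
#' @return Mean AUC across usable folds.
#' @export
cv_auc <- function(scores, peptides, region = NULL, folds = 10L, seed = 1L,
                   junction = c("include", "exclude")) {
  junction <- match.arg(junction)
  if (inherits(scores, "fscm_scorecard")) {
    region <- scores$region
    scores <- scores$scores
  }
  region <- region_spec(region)
  if (folds < 2L) stop("folds must be at least 2.", call. = FALSE)
  if (folds > nrow(peptides)) {
    stop("More folds than peptides.", call. = FALSE)
  }
  mat <- composition_matrix(peptides, region, junction = junction)
  s <- as.vector(mat %*% scores[colnames(mat)])
  fold_id <- stratified_folds(peptides$label, folds, seed)
  ok <- !seq_len(nrow(peptides)) %in% attr(mat, "unscorable")
  aucs <- vapply(seq_len(folds), function(k) {
    in_fold <- fold_id == k & ok
    lab <- peptides$label[in_fold]
    if (!all(c("positive", "negative") %in% lab)) {
      return(NA_real_)
    }
    roc_auc(s[in_fold], lab)$auc
  }, numeric(1))
  if (anyNA(aucs)) {
    warning(sum(is.na(aucs)), " fold(s) lacked a class and were skipped.",
            call. = FALSE)
  }
  mean(aucs, na.rm = TRUE)
}

# deterministic stratified fold assignment: within each class, shuffle and
# deal round-robin so fold sizes differ by at most one per class
stratified_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

#' Cross-validate the full scorecard pipeline
#'
#' For each stratified fold: build an initial scorecard on the fold's
#' training part, optionally refine it by genetic algorithm, fit the
#' threshold on the training part, and evaluate on the held-out fold.
#'
#' @param peptides Labeled peptide tibble.
#' @param region Region name or spec.
#' @param config A [ga_config()]; `cv_folds` and `seed` control the fold
#'   structure.
#' @param optimize Run GA refinement per fold (default `FALSE`: initial
#'   scorecards only, which is fast and deterministic).
#' @param junction NC junction convention.
#' @return A list with `folds` (per-fold metrics tibble) and `summary`
#'   (mean of each metric across folds).
#' @export
cross_validate <- function(peptides, region, config = ga_config(),
                           optimize = FALSE,
                           junction = c("include", "exclude")) {
  junction <- match.arg(junction)
  region <- region_spec(region)
  folds <- config$cv_folds
  fold_id <- stratified_folds(peptides$label, folds, config$seed)
  per_fold <- purrr::map_dfr(seq_len(folds), function(k) {
    train <- peptides[fold_id != k, , drop = FALSE]
    test <- peptides[fold_id == k, , drop = FALSE]
    card <- initial_scorecard(train, region, junction = junction)
    if (optimize) {
      cfg <- config
      cfg$seed <- config$seed + k
      card <- optimize_scorecard(card, train, cfg,
                                 junction = junction)$best_card
    }
    ev <- evaluate_scorecard(test, card, junction = junction)
    dplyr::mutate(ev$metrics, fold = k, .before = 1)
  })
  summary <- dplyr::summarise(
    per_fold,
    dplyr::across(c("threshold", "ac", "sn", "sp", "mcc", "auc"), mean))
  list(folds = per_fold, summary = summary)
}
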
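test_that("score_peptides is a composition-weighted mean of card scores", {
  const <- new_scorecard(rep(250, 400), "DPS", threshold = 100,
                         provenance = "external")
  got <- score_peptides(c("KAKLF", "ACDEFGHIKL"), const)
  expect_equal(got$score, c(250, 250)) # weighted mean of a constant

  one <- stats::setNames(rep(0, 400), canonical_symbols("dipeptide"))
  one["AA"] <- 100
  card_aa <- new_scorecard(one, "DPS", provenance = "external")
  expect_equal(score_peptides("AAA", card_aa)$score, 100)

  two <- stats::setNames(rep(0, 400), canonical_symbols("dipeptide"))
  two["AC"] <- 200
  two["CA"] <- 600
  card_ac <- new_scorecard(two, "DPS", provenance = "external")
  expect_equal(score_peptides("ACA", card_ac)$score, 0.5 * 200 + 0.5 * 600)
})

test_that("scores are bounded by the card range and depend only on
           composition", {
  set <- separable_set(6)
  card <- initial_scorecard(set, "DPS")
  sc <- score_peptides(set, card)
  expect_true(all(sc$score >= min(card$scores)))
  expect_true(all(sc$score <= max(card$scores)))
  # sequences with identical dipeptide composition get identical scores
  expect_equal(dpc("ACACA"), dpc("CACAC"))
  expect_equal(score_peptides("ACACA", card)$score,
               score_peptides("CACAC", card)$score,
               tolerance = 1e-9)
})

test_that("raw-count weighting scales with length, composition does not", {
  const <- new_scorecard(rep(100, 400), "DPS", provenance = "external")
  comp <- score_peptides(c("AAA", "AAAAAAA"), const)$score
  cnt <- score_peptides(c("AAA", "AAAAAAA"), const,
                        weighting = "count")$score
  expect_equal(comp, c(100, 100))
  expect_equal(cnt, c(200, 600)) # (L - 1) * 100
})

test_that("classification is strict: ties go negative", {
  expect_equal(classify(645, 311), "positive")
  expect_equal(classify(311, 311), "negative")
  expect_equal(classify(0, 311), "negative")
  expect_true(is.na(classify(500, NA)))
})

test_that("unscorable region slices are flagged, not dropped", {
  card <- new_scorecard(rep(500, 400), "DPS", threshold = 100,
                        provenance = "external")
  got <- score_peptides(peptide_tbl(pos = c("KA", "KAKLF")), card)
  expect_false(any(got$unscorable))
  # a 1-residue N-slice cannot happen (window >= 5), but a dipeptide card
  # scored on sequences of length 1 after slicing is impossible by
  # validation; simulate via direct matrix call on a short slice
  m <- composition_matrix("K", "DPS")
  expect_equal(attr(m, "unscorable"), 1L)
  expect_true(all(is.na(m[1, ])))
})

test_that("confusion_metrics matches hand-computed and oracle values", {
  perfect <- confusion_metrics(rep(c("positive", "negative"), each = 10),
                               rep(c("positive", "negative"), each = 10))
  expect_equal(perfect[, c("ac", "sn", "sp", "mcc")],
               tibble::tibble(ac = 1, sn = 1, sp = 1, mcc = 1))

  # tp=3, tn=2, fp=1, fn=0 -> MCC = 6 / sqrt(72)
  truth <- c(rep("positive", 3), rep("negative", 3))
  pred <- c(rep("positive", 3), "positive", "negative", "negative")
  m <- confusion_metrics(truth, pred)
  expect_equal(m$tp, 3)
  expect_equal(m$fp, 1)
  expect_equal(m$mcc, 6 / sqrt(72))

  all_pos <- suppressWarnings(
    confusion_metrics(rep(c("positive", "negative"), each = 5),
                      rep("positive", 10)))
  expect_equal(all_pos$sn, 1)
  expect_equal(all_pos$sp, 0)
  expect_warning(
    mcc0 <- confusion_metrics(rep(c("positive", "negative"), each = 5),
                              rep("positive", 10))$mcc,
    "denominator")
  expect_equal(mcc0, 0)
  expect_error(confusion_metrics("positive", c("positive", "negative")),
               "same length")
})

test_that("MCC equals the closed form on random confusion tables and is
           invariant to swapping both label vectors", {
  withr::with_seed(99, {
    for (i in 1:300) {
      counts <- sample(0:30, 4, replace = TRUE)
      if (sum(counts) == 0) counts[1] <- 1
      truth <- rep(c("positive", "positive", "negative", "negative"), counts)
      pred <- rep(c("positive", "negative", "negative", "positive"), counts)
      got <- suppressWarnings(confusion_metrics(truth, pred))
      expect_equal(got$mcc,
                   mcc_oracle(counts[1], counts[3], counts[4], counts[2]),
                   tolerance = 1e-12)
      # swapping positive/negative in both truth and prediction fixes MCC
      flip <- function(x) ifelse(x == "positive", "negative", "positive")
      swapped <- suppressWarnings(confusion_metrics(flip(truth), flip(pred)))
      expect_equal(swapped$mcc, got$mcc, tolerance = 1e-12)
      expect_equal(c(swapped$sn, swapped$sp), c(got$sp, got$sn))
    }
  })
})

test_that("roc_auc equals the brute-force pairwise oracle, with ties", {
  expect_equal(roc_auc(c(3, 4, 1, 2),
                       c("positive", "positive", "negative",
                         "negative"))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4),
                       c("positive", "positive", "negative",
                         "negative"))$auc, 0)
  expect_equal(roc_auc(c(1, 3, 2, 4),
                       c("positive", "positive", "negative",
                         "negative"))$auc, 0.25)
  withr::with_seed(17, {
    for (i in 1:40) {
      n <- sample(4:200, 1)
      truth <- rep("negative", n)
      truth[sample(n, max(1, min(n - 1, rbinom(1, n, 0.5))))] <- "positive"
      scores <- sample(round(stats::rnorm(n), 1)) # coarse: many ties
      got <- roc_auc(scores, truth)
      expect_equal(got$auc, auc_bruteforce(scores, truth), tolerance = 1e-9)
      # the swept ROC curve integrates to the same area
      expect_equal(fscm:::roc_trapezoid_area(got), got$auc,
                   tolerance = 1e-9)
    }
  })
  expect_error(roc_auc(1:3, rep("positive", 3)), "both classes")
})

test_that("roc_auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    for (i in 1:10) {
      n <- 60
      truth <- rep(c("positive", "negative"), c(25, 35))
      scores <- round(stats::rnorm(n), 1)
      ours <- roc_auc(scores, truth)$auc
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = truth, predictor = scores,
        levels = c("negative", "positive"), direction = "<", quiet = TRUE)))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("select_threshold maximizes training accuracy over midpoints", {
  expect_equal(select_threshold(c(900, 800, 100, 200),
                                rep(c("positive", "negative"), each = 2)),
               500)
  expect_equal(select_threshold(c(10, 0), c("positive", "negative")), 5)
  expect_warning(
    same <- select_threshold(c(7, 7), c("positive", "negative")),
    "identical")
  expect_equal(same, 7)

  # brute-force check: no candidate cutoff beats the selected one
  withr::with_seed(31, {
    for (i in 1:25) {
      n <- sample(6:60, 1)
      labels <- rep(c("positive", "negative"), length.out = n)
      scores <- round(stats::runif(n, 0, 1000), -1)
      if (length(unique(scores)) < 2) next
      th <- select_threshold(scores, labels)
      acc_at <- function(t) mean((scores > t) == (labels == "positive"))
      grid <- sort(unique(c(scores, scores - 0.5, scores + 0.5, th)))
      expect_true(all(acc_at(th) >= sapply(grid, acc_at) - 1e-12))
      # interleaved or not, accuracy never falls below the majority rate
      expect_gte(acc_at(th), max(mean(labels == "positive"),
                                 mean(labels == "negative")) - 1e-12)
    }
  })
})

test_that("evaluate_scorecard returns the full deterministic metric suite", {
  set <- separable_set(10)
  card <- initial_scorecard(set, "DPS")
  ev <- evaluate_scorecard(set, card)
  expect_equal(ev$metrics$ac, 1)
  expect_equal(ev$metrics$sn, 1)
  expect_equal(ev$metrics$sp, 1)
  expect_equal(ev$metrics$mcc, 1)
  expect_equal(ev$metrics$auc, 1)

  high <- card
  high$threshold <- 2000
  ev2 <- suppressWarnings(evaluate_scorecard(set, high))
  expect_equal(ev2$metrics$sn, 0)
  expect_equal(ev2$metrics$sp, 1)

  expect_identical(glance(evaluate_scorecard(set, card)), glance(ev))
  expect_error(
    evaluate_scorecard(set, initial_scorecard(set, "DPS",
                                              fit_threshold = FALSE)),
    "no threshold")
})

test_that("cv_auc averages per-fold AUCs of fixed scores", {
  set <- separable_set(15)
  card <- initial_scorecard(set, "DPS", fit_threshold = FALSE)
  expect_equal(cv_auc(card, set, folds = 5, seed = 1), 1) # fully separable
  expect_error(cv_auc(card, set, folds = 1, seed = 1), "at least 2")
  expect_error(cv_auc(card, set, folds = nrow(set) + 1, seed = 1),
               "More folds than peptides")
})

test_that("cv_auc is calibrated near 0.5 when scores are label-independent", {
  set <- generate_peptides(synthetic_config(effect_size = 1,
                                            n_positive = 200,
                                            n_negative = 200, seed = 4))
  withr::with_seed(4, {
    rnd <- stats::setNames(stats::runif(400, 0, 1000),
                           canonical_symbols("dipeptide"))
  })
  card <- new_scorecard(rnd, "DPS", provenance = "external")
  auc <- cv_auc(card, set, folds = 10, seed = 4)
  expect_gt(auc, 0.5 - 0.07)
  expect_lt(auc, 0.5 + 0.07)
})

test_that("cross_validate reports per-fold and mean metrics", {
  set <- separable_set(20)
  cv <- cross_validate(set, "DPS", ga_config(cv_folds = 5, seed = 2))
  expect_equal(nrow(cv$folds), 5)
  expect_equal(cv$summary$ac, 1)
  expect_equal(cv$summary$auc, 1)
})
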
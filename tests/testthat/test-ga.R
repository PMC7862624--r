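test_that("ga_config validates its invariants", {
  cfg <- ga_config()
  expect_equal(cfg$w1, 0.9)
  expect_equal(cfg$w2, 0.1)
  expect_equal(cfg$cv_folds, 10L)
  expect_equal(cfg$n_runs, 10L)
  expect_error(ga_config(population_size = 1), "at least 2")
  expect_error(ga_config(elitism_count = 100, population_size = 100),
               "elitism_count")
  expect_error(ga_config(cv_folds = 1), "at least 2")
})

test_that("fitness combines AUC and correlation with the stated weights", {
  set <- separable_set(10)
  card <- initial_scorecard(set, "DPS", fit_threshold = FALSE)
  cfg <- ga_config(auc_method = "full")
  # candidate == init: R = 1 and (separable data) AUC = 1, so F = w1 + w2
  f_self <- scorecard_fitness(card$scores, card$scores, set, "DPS", cfg)
  expect_equal(f_self, 0.9 * 1 + 0.1 * 1)

  # reversed candidate: perfectly anti-correlated with init (R = -1) and,
  # being a monotone reversal of the scores, AUC flips to 0
  rev_cand <- 1000 - card$scores
  f_rev <- scorecard_fitness(rev_cand, card$scores, set, "DPS", cfg)
  auc_rev <- roc_auc(score_peptides(set, new_scorecard(
    rev_cand, "DPS", provenance = "external"))$score, set$label)$auc
  expect_equal(f_rev, 0.9 * auc_rev + 0.1 * (-1), tolerance = 1e-9)

  # constant candidate: correlation undefined, treated as 0 with a warning,
  # so only the AUC term survives (computed on the same peptide scores)
  expect_warning(
    f_const <- scorecard_fitness(rep(500, 400), card$scores, set, "DPS",
                                 cfg),
    "[Cc]onstant")
  s_const <- as.vector(composition_matrix(set, "DPS") %*% rep(500, 400))
  expect_equal(f_const, 0.9 * roc_auc(s_const, set$label)$auc,
               tolerance = 1e-9)
})

test_that("weighted-fitness arithmetic is w1*AUC + w2*R", {
  # direct arithmetic contract on the combination rule
  cfg <- ga_config()
  expect_equal(cfg$w1 * 0.8 + cfg$w2 * 0.5, 0.77)
})

test_that("zero generations returns the initial scores with a threshold", {
  set <- separable_set(8)
  init <- initial_scorecard(set, "DPS", fit_threshold = FALSE)
  opt <- optimize_scorecard(init, set, ga_config(generations = 0,
                                                 auc_method = "full"))
  expect_equal(opt$best_card$scores, init$scores)
  expect_false(is.na(opt$best_card$threshold))
  expect_equal(opt$best_card$provenance, "optimized")
  expect_length(opt$fitness_trace, 1)
})

test_that("GA runs are deterministic for a fixed seed", {
  set <- generate_peptides(synthetic_config(n_positive = 40,
                                            n_negative = 40, seed = 2))
  init <- initial_scorecard(set, "DPS", fit_threshold = FALSE)
  cfg <- ga_config(population_size = 12, generations = 4,
                   auc_method = "full", seed = 5)
  a <- optimize_scorecard(init, set, cfg)
  b <- optimize_scorecard(init, set, cfg)
  expect_identical(a$best_card$scores, b$best_card$scores)
  expect_identical(a$fitness_trace, b$fitness_trace)
  expect_identical(a$best_card$threshold, b$best_card$threshold)
})

test_that("elitism makes the fitness trace non-decreasing and fitness
           never falls below the initial card's", {
  set <- generate_peptides(synthetic_config(n_positive = 50,
                                            n_negative = 50, seed = 9))
  init <- initial_scorecard(set, "DPS", fit_threshold = FALSE)
  cfg <- ga_config(population_size = 16, generations = 6,
                   auc_method = "full", seed = 1)
  f_init <- scorecard_fitness(init$scores, init$scores, set, "DPS", cfg)
  opt <- optimize_scorecard(init, set, cfg)
  expect_true(all(diff(opt$fitness_trace) >= 0))
  expect_gte(opt$fitness, f_init - 1e-12)
  expect_equal(opt$fitness,
               0.9 * opt$final_auc + 0.1 * opt$final_correlation,
               tolerance = 1e-9)
})

test_that("evolved scores stay on the 0-1000 scale", {
  set <- separable_set(10)
  init <- initial_scorecard(set, "DPS", fit_threshold = FALSE)
  opt <- optimize_scorecard(init, set,
                            ga_config(population_size = 10, generations = 5,
                                      mutation_rate = 0.5,
                                      mutation_sigma = 400,
                                      auc_method = "full", seed = 3))
  expect_true(all(opt$best_card$scores >= 0))
  expect_true(all(opt$best_card$scores <= 1000))
})

test_that("with pure-correlation fitness the optimizer stays at the
           initial card", {
  set <- separable_set(10)
  init <- initial_scorecard(set, "DPS", fit_threshold = FALSE)
  opt <- optimize_scorecard(init, set,
                            ga_config(population_size = 10, generations = 5,
                                      w1 = 0, w2 = 1, auc_method = "full",
                                      seed = 8))
  # R = 1 is attainable only by affine images of init; the exact init copy
  # in the population already achieves it, so fitness is 1 throughout
  expect_equal(opt$fitness, 1, tolerance = 1e-12)
  expect_equal(unname(stats::cor(opt$best_card$scores, init$scores)), 1,
               tolerance = 1e-9)
})

test_that("multirun returns n_runs reproducible results and flags the
           argmax", {
  set <- generate_peptides(synthetic_config(n_positive = 30,
                                            n_negative = 30, seed = 6))
  init <- initial_scorecard(set, "DPS", fit_threshold = FALSE)
  cfg <- ga_config(population_size = 8, generations = 2,
                   auc_method = "full", seed = 10, n_runs = 3)
  mr <- multirun_optimize(init, set, cfg)
  expect_length(mr$runs, 3)
  fits <- vapply(mr$runs, function(r) r$fitness, numeric(1))
  expect_equal(mr$selected, which.max(fits))
  expect_identical(mr$best$fitness, max(fits))
  mr2 <- multirun_optimize(init, set, cfg)
  expect_identical(fits, vapply(mr2$runs, function(r) r$fitness,
                                numeric(1)))

  single <- multirun_optimize(init, set, ga_config(
    population_size = 8, generations = 2, auc_method = "full",
    seed = 10, n_runs = 1))
  direct <- optimize_scorecard(init, set, ga_config(
    population_size = 8, generations = 2, auc_method = "full", seed = 11))
  expect_identical(single$best$best_card$scores, direct$best_card$scores)
})

test_that("optimization tidiers expose the trace and summary", {
  set <- separable_set(8)
  init <- initial_scorecard(set, "DPS", fit_threshold = FALSE)
  opt <- optimize_scorecard(init, set, ga_config(
    population_size = 6, generations = 3, auc_method = "full", seed = 1))
  td <- tidy(opt)
  expect_equal(td$generation, 0:3)
  expect_equal(td$best_fitness, opt$fitness_trace)
  gl <- glance(opt)
  expect_equal(gl$fitness, opt$fitness)
  expect_equal(gl$generations, 3)
})
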
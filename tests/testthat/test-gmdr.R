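test_that("scores are null-model response residuals", {
  # no covariates, 50/50 classes: scores are +/- 0.5 and sum to 0
  y <- rep(c(0L, 1L), 25)
  s <- compute_scores(y)
  expect_equal(sort(unique(s)), c(-0.5, 0.5))
  expect_lt(abs(sum(s)), 1e-6 * length(y))

  # with covariates: match an independently-constructed glm fit to 1e-8
  withr::with_seed(51, {
    n <- 400
    age <- stats::rnorm(n, 50, 8)
    bmi <- stats::rnorm(n, 24, 3)
    y <- stats::rbinom(n, 1, stats::plogis(-2 + 0.03 * (age - 50)))
  })
  s <- compute_scores(y, data.frame(age = age, bmi = bmi))
  oracle <- y - stats::fitted(stats::glm(y ~ age + bmi,
                                         family = stats::binomial()))
  expect_equal(s, unname(oracle), tolerance = 1e-8)
  expect_lt(abs(sum(s)), 1e-6 * n)
})

test_that("cell pooling follows the score-sum threshold with ties low", {
  toy <- balanced_toy(20, 1, seed = 52)
  scores <- compute_scores(toy$y)
  part <- partition_cells(toy$g, "snp1", scores)
  mat <- unclass(toy$g)[, 1]
  for (cell in 1:3) {
    in_cell <- mat == cell - 1L
    expected <- sum(in_cell) > 0 && sum(scores[in_cell]) > 0
    expect_identical(unname(part$high[cell]), expected)
  }
  # a cell with 3 cases (+0.5) and 1 control (-0.5) sums to 1 -> high
  g1 <- genotype_matrix(
    matrix(c(0L, 0L, 0L, 0L), 4, 1, dimnames = list(paste0("S", 1:4), "snp1")),
    toy_specs(0.3))
  p1 <- partition_cells(g1, "snp1", c(0.5, 0.5, 0.5, -0.5))
  expect_true(p1$high[1])
  # empty cells are low
  expect_false(any(p1$high[2:3]))
  expect_false(any(p1$observed[2:3]))
})

test_that("balanced accuracy is (sensitivity + specificity) / 2", {
  # TP=3 FN=1 TN=2 FP=2 -> 0.625
  g <- genotype_matrix(
    matrix(c(rep(0L, 5), rep(1L, 3)), 8, 1,
           dimnames = list(paste0("S", 1:8), "snp1")),
    toy_specs(0.3))
  # cell 0 high, cell 1 low
  part <- structure(list(high = c(TRUE, FALSE, FALSE),
                         observed = c(TRUE, TRUE, FALSE),
                         combo = "snp1", threshold = 0),
                    class = "cell_partition")
  y <- c(1, 1, 1, 0, 0, 1, 0, 0) # cell0: TP 3, FP 2; cell1: FN 1, TN 2
  expect_equal(balanced_accuracy(part, g, y), 0.625)
  # all-low prediction with both classes present -> 0.5
  part$high[] <- FALSE
  expect_equal(balanced_accuracy(part, g, y), 0.5)
  # a fold without controls is an error
  expect_error(balanced_accuracy(part, g, rep(1, 8)), "undefined")
})

test_that("GMDR equals the classic-MDR oracle on balanced subsamples", {
  # exhaustive small instances: <= 3 SNPs, <= 60 subjects, 1:1 classes
  for (seed in 1:12) {
    k <- 1 + seed %% 3
    toy <- balanced_toy(10 + 2 * (seed %% 11), k, seed = 500 + seed)
    scores <- compute_scores(toy$y)
    for (combo in utils::combn(colnames(toy$g), k, simplify = FALSE)) {
      part <- partition_cells(toy$g, combo, scores)
      orac <- oracle_mdr(unclass(toy$g), toy$y, combo)
      expect_identical(unname(part$high), unname(orac$high == 1))
      expect_equal(balanced_accuracy(part, toy$g, toy$y), orac$ba)
    }
  }
})

test_that("sign test equals the binomial tail for all n <= 20", {
  for (n in c(1, 5, 10, 20)) {
    for (k in 0:n) {
      oracle <- sum(choose(n, k:n)) / 2^n
      expect_equal(sign_test(k, n), oracle, tolerance = 1e-12)
    }
  }
  expect_equal(sign_test(10, 10), 1 / 1024)
  expect_equal(sign_test(8, 10), 56 / 1024)
  expect_equal(sign_test(0, 10), 1)
  expect_equal(sign_test(5, 10), 638 / 1024)
})

test_that("cross-validation is deterministic and order-invariant", {
  specs <- toy_specs(c(0.3, 0.3))
  g <- simulate_genotypes(600, specs, seed = 53)
  model <- disease_model(
    epistasis_terms = list(xor_epistasis("snp1", "snp2", 1)),
    prevalence_target = 0.3)
  cohort <- simulate_outcome(g, model, seed = 54)
  y <- cohort$case
  scores <- compute_scores(y)
  folds <- make_folds(rownames(g), y, 10, seed = 55)
  r1 <- cross_validate(g, c("snp1", "snp2"), scores, y, folds)
  r2 <- cross_validate(g, c("snp1", "snp2"), scores, y, folds)
  expect_identical(r1, r2)

  # permuting subject order changes nothing: folds key on subject id
  perm <- withr::with_seed(56, sample.int(nrow(g)))
  gp <- g[perm, , drop = FALSE]
  foldsp <- make_folds(rownames(gp), y[perm], 10, seed = 55)
  expect_identical(unname(foldsp), unname(folds[perm]))
  r3 <- cross_validate(gp, c("snp1", "snp2"), scores[perm], y[perm], foldsp)
  expect_equal(r1$trba, r3$trba, tolerance = 1e-12)
  expect_equal(r1$teba, r3$teba, tolerance = 1e-12)
  expect_identical(r1$fold_wins, r3$fold_wins)
})

test_that("folds are stratified and reject a class smaller than n_folds", {
  y <- c(rep(1L, 30), rep(0L, 170))
  ids <- sprintf("P%03d", 1:200)
  folds <- make_folds(ids, y, 10, seed = 57)
  per_fold_cases <- table(folds[y == 1])
  expect_true(all(per_fold_cases == 3))
  expect_error(make_folds(ids[1:15], c(rep(1L, 5), rep(0L, 10)), 10, 1),
               "fewer subjects than folds")
})

test_that("the exhaustive search counts C(m, k) subsets and finds a
           planted additive SNP at k = 1", {
  specs <- toy_specs(rep(0.3, 5))
  g <- simulate_genotypes(3000, specs, seed = 58)
  model <- disease_model(snp_log_or = c(snp3 = 0.9),
                         prevalence_target = 0.2)
  cohort <- simulate_outcome(g, model, seed = 59)
  res <- search_best_models(g, cohort$case, k_range = 1:2, seed = 60)
  expect_identical(res$n_evaluated, c(5L, 10L))
  expect_identical(res$model[1], "snp3")
  expect_true(all(res$trba >= 0 & res$trba <= 1))
  expect_true(all(res$cvc >= 0 & res$cvc <= 10))
})

test_that("a planted epistatic pair wins the k = 2 exhaustive search", {
  specs <- toy_specs(rep(0.4, 6))
  g <- simulate_genotypes(4000, specs, seed = 61)
  model <- disease_model(
    epistasis_terms = list(xor_epistasis("snp2", "snp5", effect = 1.0)),
    prevalence_target = 0.15)
  cohort <- simulate_outcome(g, model, seed = 62)
  res <- search_best_models(g, cohort$case, k_range = 2, seed = 63)
  expect_identical(res$model, "snp2 snp5")
  expect_gt(res$teba, 0.5)
  expect_lt(res$sign_p, 0.05)
})

test_that("TRBA dominates TEBA in expectation on null data", {
  diffs <- vapply(1:120, function(s) {
    g <- simulate_genotypes(300, toy_specs(c(0.3, 0.3)), seed = 3000 + s)
    y <- withr::with_seed(4000 + s, stats::rbinom(300, 1, 0.3))
    if (sum(y) < 10 || sum(1 - y) < 10) return(NA_real_)
    scores <- compute_scores(y)
    folds <- make_folds(rownames(g), y, 10, seed = s)
    r <- cross_validate(g, c("snp1", "snp2"), scores, y, folds)
    r$trba - r$teba
  }, 0)
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})

test_that("mean test balanced accuracy is ~0.5 on null genotypes", {
  tebas <- vapply(1:60, function(s) {
    g <- simulate_genotypes(400, toy_specs(c(0.3, 0.3)), seed = 5000 + s)
    y <- withr::with_seed(6000 + s, stats::rbinom(400, 1, 0.3))
    scores <- compute_scores(y)
    folds <- make_folds(rownames(g), y, 10, seed = s)
    cross_validate(g, c("snp1", "snp2"), scores, y, folds)$teba
  }, 0)
  expect_equal(mean(tebas), 0.5, tolerance = 0.02)
})

test_that("forward search reproduces the nested model sequence", {
  specs <- toy_specs(rep(0.3, 5))
  g <- simulate_genotypes(2500, specs, seed = 64)
  model <- disease_model(snp_log_or = c(snp1 = 0.7, snp4 = 0.5),
                         prevalence_target = 0.2)
  cohort <- simulate_outcome(g, model, seed = 65)
  res <- search_best_models(g, cohort$case, k_range = 1:3, seed = 66,
                            strategy = "forward")
  models <- strsplit(res$model, " ")
  expect_true(all(models[[1]] %in% models[[2]]))
  expect_true(all(models[[2]] %in% models[[3]]))
  expect_identical(res$n_evaluated, c(5L, 4L, 3L))
})
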
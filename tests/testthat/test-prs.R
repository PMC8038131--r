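test_that("risk alleles are oriented by the direction of the OR", {
  screen <- data.frame(
    snp_id = c("rs_minor_risk", "rs_major_risk"),
    minor_allele = c("C", "T"),
    major_allele = c("G", "C"),
    or = c(1.29, 0.76))
  model <- orient_risk_alleles(screen, screen$snp_id)
  expect_identical(model$risk_allele, c("C", "C"))
  expect_identical(model$risk_is_minor, c(TRUE, FALSE))

  screen$or[1] <- 1
  expect_error(orient_risk_alleles(screen, screen$snp_id), "manual")
})

test_that("PRS counts risk alleles 0/1/2 per SNP and sums them", {
  specs <- snp_specs(paste0("s", 1:6), rep("1", 6), 1:6 * 100L,
                     minor_allele = rep("G", 6), major_allele = rep("T", 6),
                     maf = rep(0.3, 6))
  screen <- data.frame(snp_id = specs$snp_id,
                       minor_allele = specs$minor_allele,
                       major_allele = specs$major_allele,
                       or = c(1.5, 1.5, 1.5, 1.5, 1.5, 0.7))
  model <- orient_risk_alleles(screen, specs$snp_id)

  mk <- function(...) {
    genotype_matrix(matrix(as.integer(c(...)), 1, 6,
                           dimnames = list("S1", specs$snp_id)), specs)
  }
  # G (minor) is the risk allele at s1: GG -> 2, GT -> 1, TT -> 0
  expect_identical(compute_prs(mk(2, 0, 0, 0, 0, 2), model)$score, 2L)
  expect_identical(compute_prs(mk(1, 0, 0, 0, 0, 2), model)$score, 1L)
  expect_identical(compute_prs(mk(0, 0, 0, 0, 0, 2), model)$score, 0L)
  # all non-risk homozygotes -> 0; all risk homozygotes -> 2m = 12
  expect_identical(compute_prs(mk(0, 0, 0, 0, 0, 2), model)$score, 0L)
  expect_identical(compute_prs(mk(2, 2, 2, 2, 2, 0), model)$score, 12L)
})

test_that("PRS is SNP-order invariant and matches a brute-force count", {
  specs <- toy_specs(rep(0.3, 4))
  g <- simulate_genotypes(300, specs, seed = 71)
  screen <- data.frame(snp_id = specs$snp_id,
                       minor_allele = specs$minor_allele,
                       major_allele = specs$major_allele,
                       or = c(1.3, 0.8, 1.1, 0.6))
  model <- orient_risk_alleles(screen, specs$snp_id)
  prs <- compute_prs(g, model)
  # brute force per subject
  mat <- unclass(g)
  brute <- vapply(seq_len(nrow(mat)), function(i) {
    s <- 0L
    for (j in seq_len(4)) {
      cnt <- mat[i, j]
      if (!model$risk_is_minor[j]) cnt <- 2L - cnt
      s <- s + cnt
    }
    s
  }, 0L)
  expect_identical(prs$score, brute)
  # permuted model rows give identical scores
  model_perm <- model[c(3, 1, 4, 2), ]
  class(model_perm) <- class(model)
  expect_identical(compute_prs(g, model_perm)$score, prs$score)
})

test_that("flipping a declared risk allele maps its component 0/1/2 -> 2/1/0", {
  specs <- toy_specs(rep(0.3, 2))
  g <- simulate_genotypes(100, specs, seed = 72)
  screen <- data.frame(snp_id = specs$snp_id,
                       minor_allele = specs$minor_allele,
                       major_allele = specs$major_allele,
                       or = c(1.4, 1.2))
  m1 <- orient_risk_alleles(screen, specs$snp_id)
  m2 <- m1
  m2$risk_is_minor[1] <- FALSE
  m2$risk_allele[1] <- "G"
  s1 <- compute_prs(g, m1)$score
  s2 <- compute_prs(g, m2)$score
  # snp1's flipped component sums to 2; snp2's is counted twice
  expect_identical(s1 + s2, unname(2L + 2L * unclass(g)[, 2]))
})

test_that("missing model genotypes exclude the subject by default", {
  specs <- toy_specs(rep(0.3, 2))
  g0 <- simulate_genotypes(50, specs, seed = 73)
  mat <- unclass(g0)
  mat[3, 1] <- NA_integer_
  g <- genotype_matrix(mat, specs)
  screen <- data.frame(snp_id = specs$snp_id,
                       minor_allele = specs$minor_allele,
                       major_allele = specs$major_allele, or = c(1.3, 1.2))
  model <- orient_risk_alleles(screen, specs$snp_id)
  prs <- compute_prs(g, model)
  expect_identical(nrow(prs), 49L)
  expect_identical(attr(prs, "dropped"), rownames(mat)[3])
  prs_imp <- compute_prs(g, model, missing = "impute")
  expect_identical(nrow(prs_imp), 50L)
})

test_that("preset tertile bands reproduce the published category bounds", {
  # 6-SNP model: 0-3 low, 4-6 medium, >= 7 high
  profiles6 <- data.frame(subject_id = paste0("S", 0:12), score = 0:12)
  cat6 <- categorize_prs(profiles6, prs_bands(6))
  expect_identical(as.character(cat6$category),
                   c(rep("low", 4), rep("medium", 3), rep("high", 6)))
  # 5-SNP model: 0-3 low, 4-5 medium, >= 6 high
  profiles5 <- data.frame(subject_id = paste0("S", 0:10), score = 0:10)
  cat5 <- categorize_prs(profiles5, prs_bands(5))
  expect_identical(as.character(cat5$category),
                   c(rep("low", 4), rep("medium", 2), rep("high", 5)))
  expect_error(prs_bands(4), "no preset")
})

test_that("empirical tertiles differ from presets only near band edges", {
  withr::with_seed(74, {
    score <- stats::rbinom(5000, 12, 0.35)
  })
  profiles <- data.frame(subject_id = sprintf("S%04d", 1:5000),
                         score = score)
  preset <- categorize_prs(profiles, prs_bands(6))
  empir <- categorize_prs(profiles, "tertile")
  bounds <- attr(empir, "bounds")
  moved <- preset$category != empir$category
  # any subject whose category moved sits between the two band edges
  edges <- sort(unique(c(3L, 6L, bounds)))
  expect_true(all(profiles$score[moved] > min(edges) - 1 &
                    profiles$score[moved] <= max(edges) + 1))
})

test_that("category ORs are monotone for an additive per-allele effect", {
  specs <- toy_specs(rep(0.35, 6))
  g <- simulate_genotypes(20000, specs, seed = 75)
  lor <- stats::setNames(rep(0.2, 6), specs$snp_id)
  model <- disease_model(snp_log_or = lor, prevalence_target = 0.1)
  cohort <- simulate_outcome(g, model, seed = 76)
  screen <- association_screen(g, cohort$case)
  pm <- orient_risk_alleles(screen, specs$snp_id)
  profiles <- categorize_prs(compute_prs(g, pm), prs_bands(6))
  ors <- prs_category_or(profiles, cohort)
  expect_identical(ors$category, c("low", "medium", "high"))
  expect_gt(ors$or[2], 1)
  expect_gt(ors$or[3], ors$or[2])
})
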
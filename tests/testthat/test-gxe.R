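test_that("dichotomization puts the cutoff value in the high group", {
  cohort <- data.frame(subject_id = paste0("S", 1:4),
                       wbc = c(3.9, 4.1, 4.0, 5.2),
                       seaweed_g = c(2.64, 2.65, 0.1, 4.0))
  cut <- dichotomize(cohort, list(exposure_cut("wbc", 4),
                                  exposure_cut("seaweed_g", 2.65)))
  expect_identical(as.character(cut$wbc_high),
                   c("low", "high", "high", "high"))
  expect_identical(as.character(cut$seaweed_g_high),
                   c("low", "high", "low", "high"))
})

test_that("percentile cutoffs are computed on the analysis sample", {
  cohort <- data.frame(subject_id = paste0("S", 1:10), pat = 1:10)
  cut <- dichotomize(cohort, list(exposure_cut("pat", percentile = 70)))
  expect_identical(sum(cut$pat_high == "high"), 3L)
})

test_that("degenerate exposures are rejected", {
  cohort <- data.frame(subject_id = c("S1", "S2"), x = c(1, 1))
  expect_error(dichotomize(cohort, list(exposure_cut("x", 0))),
               "one side")
  expect_error(dichotomize(cohort, list(exposure_cut("absent", 1))),
               "absent")
})

# shared fixture: cohort with genotype-derived PRS categories and a
# binary exposure, with an optional planted PRS x exposure interaction
gxe_cohort <- function(n, seed, interaction_lor = 0, prs_lor = 0.35,
                       prevalence = 0.15) {
  specs <- toy_specs(rep(0.35, 6))
  g <- simulate_genotypes(n, specs, seed = seed)
  expo <- withr::with_seed(seed + 1, stats::rbinom(n, 1, 0.5))
  score <- rowSums(unclass(g))
  cat012 <- as.integer(cut(score, c(-Inf, 3, 6, Inf))) - 1L
  eta <- prs_lor * cat012 + 0.1 * expo + interaction_lor * cat012 * expo
  intercept <- stats::qlogis(prevalence) - mean(eta)
  y <- withr::with_seed(seed + 2, stats::rbinom(n, 1,
                                                stats::plogis(intercept + eta)))
  cohort <- data.frame(subject_id = rownames(g), case = y,
                       expo = factor(ifelse(expo == 1, "high", "low"),
                                     levels = c("low", "high")),
                       age = withr::with_seed(seed + 3,
                                              stats::rnorm(n, 50, 8)))
  screen <- data.frame(snp_id = specs$snp_id,
                       minor_allele = specs$minor_allele,
                       major_allele = specs$major_allele,
                       or = rep(1.4, 6))
  pm <- orient_risk_alleles(screen, specs$snp_id)
  profiles <- categorize_prs(compute_prs(g, pm), prs_bands(6))
  list(profiles = profiles, cohort = cohort)
}

test_that("stratified grid covers every stratum x category with low as 1", {
  fx <- gxe_cohort(12000, seed = 81, interaction_lor = 0.8)
  grid <- stratified_prs_or(fx$profiles, fx$cohort, "expo",
                            covariates = "age")
  expect_identical(nrow(grid), 6L)
  expect_setequal(unique(grid$stratum), c("low", "high"))
  low_rows <- grid[grid$category == "low", ]
  expect_true(all(low_rows$or == 1))
  # planted interaction: high-PRS OR larger in the high-exposure stratum
  hi <- grid[grid$category == "high", ]
  expect_gt(hi$or[hi$stratum == "high"], hi$or[hi$stratum == "low"])
})

test_that("pooled strata reproduce the unstratified category ORs", {
  fx <- gxe_cohort(8000, seed = 82)
  pooled <- prs_category_or(fx$profiles, fx$cohort, covariates = "age")
  # refit with the exposure as covariate only (no product terms)
  both <- prs_category_or(fx$profiles, fx$cohort,
                          covariates = c("age", "expo"))
  expect_equal(pooled$or[2:3], both$or[2:3], tolerance = 0.1)
})

test_that("a strong planted interaction is detected", {
  hits <- vapply(1:20, function(s) {
    fx <- gxe_cohort(20000, seed = 8200 + 7 * s, interaction_lor = 1.0)
    interaction_test(fx$profiles, fx$cohort, "expo",
                     covariates = "age")$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("LR and Wald interaction tests agree on well-conditioned fits", {
  fx <- gxe_cohort(20000, seed = 83, interaction_lor = 0.6)
  p_lr <- interaction_test(fx$profiles, fx$cohort, "expo",
                           covariates = "age")$p
  p_wald <- interaction_test(fx$profiles, fx$cohort, "expo",
                             covariates = "age", test = "wald")$p
  expect_lt(abs(log10(max(p_lr, 1e-300)) - log10(max(p_wald, 1e-300))), 1)
})

test_that("a covariate duplicating the exposure is a rank-deficiency error", {
  fx <- gxe_cohort(3000, seed = 84)
  fx$cohort$expo_copy <- fx$cohort$expo
  expect_error(interaction_test(fx$profiles, fx$cohort, "expo",
                                covariates = c("age", "expo_copy")),
               "rank-deficient")
})

test_that("categorical PRS coding uses two interaction df", {
  fx <- gxe_cohort(6000, seed = 85, interaction_lor = 0.5)
  r1 <- interaction_test(fx$profiles, fx$cohort, "expo",
                         covariates = "age")
  r2 <- interaction_test(fx$profiles, fx$cohort, "expo",
                         covariates = "age", prs_coding = "categorical")
  expect_identical(r1$df, 1L)
  expect_identical(r2$df, 2L)
})
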
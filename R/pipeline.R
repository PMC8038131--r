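# End-to-end drivers: generate a synthetic study and run the whole
# screen -> LD prune -> GMDR -> PRS -> interaction pipeline.

#' Simulate a full synthetic study
#'
#' Generates a case-control cohort with the structure the pipeline
#' assumes: the ten-SNP thyroid panel at its published MAFs under HWE,
#' additive per-SNP effects at the published odds ratios, an optional
#' planted two-locus epistatic term, lifestyle exposures, food-group
#' intakes with four latent dietary patterns, and a case prevalence of
#' 0.9% as in the source cohort (495 cases among 56,934 subjects).
#'
#' @param n_subjects cohort size (default 56934).
#' @param specs SNP panel (default [thyroid_snp_panel()]).
#' @param seed integer seed; sub-stages derive distinct seeds from it.
#' @param prevalence target case fraction (default 0.009).
#' @param snp_log_or named per-SNP log ORs; default `log(published_or)`
#'   of the panel where available, none otherwise.
#' @param epistasis_terms list of [epistasis_cells()] terms (default a
#'   checkerboard interaction of +0.8 log-odds between rs7834206 and
#'   rs72616195, two SNPs of the reported best model).
#' @param ld_blocks optional LD blocks for [simulate_genotypes()].
#' @param exposure_specs exposure panel
#'   (default [default_exposure_specs()]).
#' @param n_food_groups,food_block_sizes,food_rho food-group generator
#'   settings (default 29 groups, four pattern blocks, rho 0.6).
#' @return list: `genotypes` (a [genotype_matrix()]), `cohort`
#'   (data.frame with subject_id, case, exposures and food groups),
#'   `manifest` (a [column_manifest()]), `model` (the disease model),
#'   `food_blocks` (latent block indices).
#' @export
simulate_study <- function(n_subjects = 56934,
                           specs = thyroid_snp_panel(),
                           seed = 1L,
                           prevalence = 0.009,
                           snp_log_or = NULL,
                           epistasis_terms = NULL,
                           ld_blocks = NULL,
                           exposure_specs = default_exposure_specs(),
                           n_food_groups = 29,
                           food_block_sizes = c(6, 5, 5, 5),
                           food_rho = 0.6) {
  seed <- as.integer(seed)
  if (is.null(snp_log_or)) {
    snp_log_or <- if ("published_or" %in% names(specs)) {
      stats::setNames(log(specs$published_or), specs$snp_id)
    } else {
      numeric()
    }
  }
  if (is.null(epistasis_terms)) {
    epistasis_terms <- if (all(c("rs7834206", "rs72616195") %in%
                                 specs$snp_id)) {
      list(xor_epistasis("rs7834206", "rs72616195", effect = 0.8))
    } else {
      list()
    }
  }
  g <- simulate_genotypes(n_subjects, specs, seed = seed,
                          ld_blocks = ld_blocks)
  exposures <- simulate_exposures(n_subjects, exposure_specs,
                                  seed = seed + 1L)
  model <- disease_model(snp_log_or = snp_log_or,
                         epistasis_terms = epistasis_terms,
                         prevalence_target = prevalence)
  cohort <- simulate_outcome(g, model, seed = seed + 2L,
                             cohort = exposures)
  foods <- simulate_food_groups(n_subjects, n_food_groups,
                                food_block_sizes, food_rho,
                                seed = seed + 3L)
  cohort <- cbind(cohort, as.data.frame(foods))
  manifest <- column_manifest(
    outcome = "case",
    covariates = c("gender", "age", "bmi"),
    exposures = vapply(exposure_specs, `[[`, "", "name"),
    food_groups = colnames(foods))
  list(genotypes = g, cohort = cohort, manifest = manifest, model = model,
       food_blocks = attr(foods, "blocks"))
}

#' Run the full pipeline on a cohort
#'
#' Association screen with QC, threshold selection, within-chromosome
#' LD pruning, exhaustive GMDR search, risk-allele PRS over the best
#' model, category odds ratios and PRS x exposure interaction tests.
#'
#' @param genotypes a [genotype_matrix()].
#' @param cohort cohort data.frame (subject_id, outcome, covariates,
#'   exposures).
#' @param covariates covariate column names for the adjusted fits.
#' @param outcome outcome column name.
#' @param p_threshold,maf_min,hwe_min screen thresholds
#'   ([select_candidates()]).
#' @param ld_threshold D' pruning threshold (default 0.4).
#' @param k_range GMDR model sizes (default 1..#candidates, capped by
#'   `k_max`).
#' @param k_max cap on model size (default 6).
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed (fold construction).
#' @param exposures optional character vector of binary exposure
#'   columns to test for interaction (e.g. from [dichotomize()]).
#' @param best_k model size to carry into the PRS (default: the k with
#'   the lowest sign-test p, ties to higher TEBA).
#' @return list with the stage outputs: screen, candidates, pruning,
#'   gmdr, best_model, prs_model, profiles, category_or, interactions.
#' @export
run_pipeline <- function(genotypes, cohort, covariates = character(),
                         outcome = "case",
                         p_threshold = 1e-3, maf_min = 0.01,
                         hwe_min = 0.05, ld_threshold = 0.4,
                         k_range = NULL, k_max = 6, n_folds = 10,
                         seed = 1L, exposures = character(),
                         best_k = NULL) {
  y <- cohort[[outcome]]
  covs <- if (length(covariates)) {
    cohort[, covariates, drop = FALSE]
  } else {
    NULL
  }
  screen <- association_screen(genotypes, y, covs)
  candidates <- select_candidates(screen, p_threshold, maf_min, hwe_min)
  if (nrow(candidates) < 1) stop("no SNP survives the screen")
  pruning <- prune_by_ld(genotypes, candidates, ld_threshold)
  kept <- pruning$kept
  g_kept <- genotypes[, kept, drop = FALSE]
  if (is.null(k_range)) k_range <- seq_len(min(length(kept), k_max))
  gmdr <- search_best_models(g_kept, y, covs, k_range = k_range,
                             n_folds = n_folds, seed = seed)
  if (is.null(best_k)) {
    ord <- order(gmdr$sign_p, -gmdr$teba)
    best_k <- gmdr$k[ord[1]]
  }
  best_row <- gmdr[gmdr$k == best_k, ]
  best_snps <- strsplit(best_row$model, " ")[[1]]
  prs_model <- orient_risk_alleles(screen, best_snps)
  profiles <- compute_prs(genotypes, prs_model)
  profiles <- categorize_prs(profiles, prs_bands_or_tertile(length(best_snps),
                                                            profiles))
  category_or <- prs_category_or(profiles, cohort, outcome, covariates)
  interactions <- lapply(exposures, function(e) {
    covs_e <- setdiff(covariates, sub("_high$", "", e))
    list(exposure = e,
         strata = stratified_prs_or(profiles, cohort, e, outcome, covs_e),
         test = interaction_test(profiles, cohort, e, outcome, covs_e))
  })
  names(interactions) <- exposures
  list(screen = screen, candidates = candidates, pruning = pruning,
       gmdr = gmdr, best_model = best_snps, prs_model = prs_model,
       profiles = profiles, category_or = category_or,
       interactions = interactions)
}

# preset tertile bands when a preset exists, empirical tertiles otherwise
prs_bands_or_tertile <- function(n_snps, profiles) {
  tryCatch(prs_bands(n_snps), error = function(e) "tertile")
}
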
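# Risk-allele-count polygenic risk score over the selected best model:
# orient each SNP's risk allele from its association odds ratio, sum
# unweighted risk-allele counts (0/1/2 per SNP), band into tertile
# categories, and estimate adjusted odds ratios per category.

#' Orient risk alleles from association effects
#'
#' The risk allele of each SNP is the allele whose carriage increases
#' disease odds: the minor allele when its additive OR exceeds 1, the
#' major allele when the OR is below 1. An OR of exactly 1 carries no
#' orientation and is rejected.
#'
#' @param screen association table (from [association_screen()])
#'   covering `snp_ids`, with columns snp_id, minor_allele,
#'   major_allele, or.
#' @param snp_ids the best-model SNPs.
#' @return data.frame of class `prs_model`: snp_id, risk_allele,
#'   risk_is_minor, or.
#' @export
orient_risk_alleles <- function(screen, snp_ids) {
  idx <- match(snp_ids, screen$snp_id)
  if (anyNA(idx)) {
    stop("no association effect for SNP(s): ",
         paste(snp_ids[is.na(idx)], collapse = ", "))
  }
  eff <- screen[idx, , drop = FALSE]
  if (any(eff$or == 1)) {
    stop("OR exactly 1 for ", paste(eff$snp_id[eff$or == 1], collapse = ", "),
         ": risk allele undefined, orient manually")
  }
  risk_is_minor <- eff$or > 1
  out <- data.frame(
    snp_id = eff$snp_id,
    risk_allele = ifelse(risk_is_minor, eff$minor_allele, eff$major_allele),
    risk_is_minor = risk_is_minor,
    or = eff$or,
    stringsAsFactors = FALSE)
  class(out) <- c("prs_model", "data.frame")
  out
}

#' Unweighted risk-allele-count PRS
#'
#' Per-subject score = sum over model SNPs of the risk-allele count
#' (0, 1 or 2). Minor-allele-coded genotypes are flipped (0/1/2 ->
#' 2/1/0) where the risk allele is the major allele. Subjects missing
#' any model genotype are excluded by default, or mean-imputed (rounded
#' per-SNP mean count) on request; either way the affected subjects are
#' recorded.
#'
#' @param g a [genotype_matrix()] containing every model SNP.
#' @param model a [orient_risk_alleles()] result.
#' @param missing `"exclude"` (default) or `"impute"`.
#' @return data.frame: subject_id, score (integer 0..2m); attribute
#'   `dropped` lists excluded subject ids.
#' @export
compute_prs <- function(g, model, missing = c("exclude", "impute")) {
  missing <- match.arg(missing)
  stopifnot(inherits(model, "prs_model"))
  absent <- setdiff(model$snp_id, colnames(g))
  if (length(absent)) {
    stop("model SNP(s) absent from genotypes: ", paste(absent, collapse = ", "))
  }
  mat <- unclass(g)[, model$snp_id, drop = FALSE]
  flip <- !model$risk_is_minor
  mat[, flip] <- 2L - mat[, flip, drop = FALSE]
  dropped <- character()
  if (anyNA(mat)) {
    if (missing == "exclude") {
      bad <- rowSums(is.na(mat)) > 0
      dropped <- rownames(mat)[bad]
      mat <- mat[!bad, , drop = FALSE]
    } else {
      for (j in seq_len(ncol(mat))) {
        nas <- is.na(mat[, j])
        if (any(nas)) mat[nas, j] <- as.integer(round(mean(mat[, j],
                                                            na.rm = TRUE)))
      }
    }
  }
  out <- data.frame(subject_id = rownames(mat),
                    score = as.integer(rowSums(mat)),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Tertile band presets
#'
#' The fixed low/medium/high score bands used with the best models:
#' a 6-SNP model is banded 0-3 / 4-6 / >=7 and a 5-SNP model
#' 0-3 / 4-5 / >=6. Bounds are the two upper inclusive limits of the
#' low and medium bands.
#'
#' @param n_snps 5 or 6 for the shipped presets.
#' @return integer length-2 vector `c(low_max, medium_max)`.
#' @export
prs_bands <- function(n_snps) {
  switch(as.character(n_snps),
         "5" = c(3L, 5L),
         "6" = c(3L, 6L),
         stop("no preset band for a ", n_snps,
              "-SNP model; pass explicit bounds to categorize_prs()"))
}

#' Band PRS scores into low/medium/high
#'
#' @param profiles data.frame from [compute_prs()].
#' @param bounds integer `c(low_max, medium_max)`, strictly increasing:
#'   score <= low_max is low, <= medium_max is medium, else high.
#'   Alternatively `bounds = "tertile"` derives empirical tertile
#'   cutpoints from the score distribution.
#' @return `profiles` with an ordered factor column `category`.
#' @export
categorize_prs <- function(profiles, bounds) {
  if (identical(bounds, "tertile")) {
    qs <- stats::quantile(profiles$score, c(1 / 3, 2 / 3), type = 1)
    bounds <- as.integer(qs)
    # integer scores can collapse the tertile cutpoints; keep the bands
    # non-degenerate when the score range allows it
    if (bounds[1] >= bounds[2]) bounds[2] <- bounds[1] + 1L
    if (bounds[1] >= max(profiles$score)) bounds[1] <- bounds[2] - 1L
  }
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  cat <- cut(profiles$score, c(-Inf, bounds[1], bounds[2], Inf),
             labels = c("low", "medium", "high"), ordered_result = TRUE)
  profiles$category <- cat
  attr(profiles, "bounds") <- bounds
  profiles
}

#' Adjusted odds ratios per PRS category
#'
#' Dummy-codes medium and high versus the low reference in an adjusted
#' logistic fit and reports Wald ORs with 95% CIs.
#'
#' @param profiles categorized profiles ([categorize_prs()]).
#' @param cohort cohort data.frame with `subject_id` and the outcome.
#' @param outcome outcome column name (default "case").
#' @param covariates character vector of covariate column names.
#' @return data.frame: category, or, ci_low, ci_high, p, n (low row has
#'   OR fixed at 1).
#' @export
prs_category_or <- function(profiles, cohort, outcome = "case",
                            covariates = character()) {
  idx <- match(profiles$subject_id, cohort$subject_id)
  if (anyNA(idx)) stop("profiles contain subjects absent from cohort")
  df <- data.frame(.y = cohort[[outcome]][idx],
                   category = profiles$category)
  for (v in covariates) df[[v]] <- cohort[[v]][idx]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  ref <- df$category == "low"
  if (sum(df$.y[ref] == 1) < 1 || sum(df$.y[ref] == 0) < 1) {
    stop("reference (low) category lacks a case or a control")
  }
  df$category <- factor(df$category, levels = c("low", "medium", "high"),
                        ordered = FALSE)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  co <- summary(fit)$coefficients
  rows <- data.frame(category = "low", or = 1, ci_low = NA_real_,
                     ci_high = NA_real_, p = NA_real_,
                     n = sum(ref), stringsAsFactors = FALSE)
  for (lev in c("medium", "high")) {
    term <- paste0("category", lev)
    if (!term %in% rownames(co)) next
    b <- co[term, "Estimate"]; se <- co[term, "Std. Error"]
    rows <- rbind(rows, data.frame(
      category = lev, or = exp(b), ci_low = exp(b - 1.96 * se),
      ci_high = exp(b + 1.96 * se), p = co[term, "Pr(>|z|)"],
      n = sum(df$category == lev), stringsAsFactors = FALSE))
  }
  rows
}
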
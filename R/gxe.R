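# Gene-environment interaction machinery: dichotomize exposures at
# declared cutoffs (or sample percentiles), estimate PRS-category odds
# ratios within exposure strata, and test PRS x exposure interaction by
# likelihood ratio in adjusted logistic models.

#' Exposure dichotomization rule
#'
#' @param name exposure column name.
#' @param cutoff numeric cutoff in the exposure's units, or NA when
#'   `percentile` is used.
#' @param percentile optional percentile (0-100) computed on the full
#'   analysis sample (e.g. 70 for diet-pattern scores).
#' @param high_side which side is "high": `"ge"` (default; high
#'   includes the cutoff value) or `"lt"`.
#' @return list of class `exposure_cut`.
#' @export
exposure_cut <- function(name, cutoff = NA_real_, percentile = NA_real_,
                         high_side = c("ge", "lt")) {
  high_side <- match.arg(high_side)
  if (is.na(cutoff) && is.na(percentile)) {
    stop("exposure_cut needs a cutoff or a percentile")
  }
  structure(list(name = name, cutoff = cutoff, percentile = percentile,
                 high_side = high_side),
            class = "exposure_cut")
}

#' Default exposure cutoffs
#'
#' The shipped dichotomization rules: white blood cell count at
#' 4 x 10^9/L, energy intake at 100% of the estimated energy
#' requirement, alcohol at 20 g/day, seaweed at 2.65 g/day, age at 55
#' years, BMI at 25 kg/m^2, and diet-pattern scores at their 70th
#' percentile.
#'
#' @param patterns character vector of diet-pattern score column names
#'   to cut at the 70th percentile.
#' @return list of [exposure_cut()] rules.
#' @export
default_exposure_cuts <- function(patterns = character()) {
  cuts <- list(
    exposure_cut("wbc", 4),
    exposure_cut("energy_pct", 100),
    exposure_cut("alcohol_g", 20),
    exposure_cut("seaweed_g", 2.65),
    exposure_cut("age", 55),
    exposure_cut("bmi", 25))
  c(cuts, lapply(patterns, function(p) exposure_cut(p, percentile = 70)))
}

#' Dichotomize exposures
#'
#' Adds a binary factor column `<name>_high` (levels low/high) per rule.
#' "High" includes the cutoff value under the default `ge` side;
#' percentile cutoffs are computed on the analysed sample. A column
#' that ends up entirely on one side is an error.
#'
#' @param cohort data.frame.
#' @param cuts list of [exposure_cut()] rules.
#' @return `cohort` with the added columns; realized cutoffs in
#'   attribute `cutoffs`.
#' @export
dichotomize <- function(cohort, cuts) {
  realized <- numeric(0)
  for (ct in cuts) {
    x <- cohort[[ct$name]]
    if (is.null(x)) stop("exposure column absent: ", ct$name)
    if (!is.numeric(x)) stop("exposure '", ct$name, "' is not numeric")
    cutoff <- if (!is.na(ct$percentile)) {
      stats::quantile(x, ct$percentile / 100, na.rm = TRUE, names = FALSE)
    } else {
      ct$cutoff
    }
    hi <- if (ct$high_side == "ge") x >= cutoff else x < cutoff
    if (all(hi, na.rm = TRUE) || all(!hi, na.rm = TRUE)) {
      stop("exposure '", ct$name, "' is entirely on one side of its cutoff")
    }
    cohort[[paste0(ct$name, "_high")]] <-
      factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
    realized[ct$name] <- cutoff
  }
  attr(cohort, "cutoffs") <- realized
  cohort
}

#' PRS-category odds ratios within exposure strata
#'
#' Fits the adjusted PRS-category logistic model separately in each
#' level of a binary exposure. Strata where the fit is not estimable
#' (empty cells, separation) are reported as non-estimable rows rather
#' than dropped.
#'
#' @param profiles categorized PRS profiles ([categorize_prs()]).
#' @param cohort cohort with `subject_id`, the outcome and the exposure
#'   column.
#' @param exposure name of a binary factor column (e.g. from
#'   [dichotomize()]).
#' @param outcome outcome column name.
#' @param covariates covariate column names.
#' @return data.frame grid: stratum x category rows with or, ci_low,
#'   ci_high, p, n, estimable.
#' @export
stratified_prs_or <- function(profiles, cohort, exposure,
                              outcome = "case", covariates = character()) {
  ex <- cohort[[exposure]]
  if (is.null(ex)) stop("exposure column absent: ", exposure)
  levs <- levels(factor(ex))
  out <- list()
  for (lv in levs) {
    keep_ids <- cohort$subject_id[!is.na(ex) & ex == lv]
    pr <- profiles[profiles$subject_id %in% keep_ids, , drop = FALSE]
    res <- tryCatch(
      prs_category_or(pr, cohort, outcome = outcome, covariates = covariates),
      error = function(e) NULL)
    if (is.null(res)) {
      res <- data.frame(category = c("low", "medium", "high"),
                        or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        n = NA_integer_, stringsAsFactors = FALSE)
      res$estimable <- FALSE
    } else {
      res$estimable <- TRUE
    }
    res$stratum <- lv
    out[[lv]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("stratum", "category", "or", "ci_low", "ci_high", "p", "n",
          "estimable")]
}

#' PRS x exposure interaction test
#'
#' Likelihood-ratio test of the adjusted logistic model with PRS x
#' exposure product terms against the main-effects-only model (Wald on
#' the product term by option). The PRS enters as an ordered 0/1/2
#' category score by default (1 df against a binary exposure);
#' `prs_coding = "categorical"` uses two dummy contrasts (2 df).
#'
#' @param profiles categorized PRS profiles.
#' @param cohort cohort data.frame.
#' @param exposure binary exposure column name.
#' @param outcome outcome column name.
#' @param covariates covariate column names; a covariate identical to
#'   the tested exposure must be dropped by the caller (a rank-deficient
#'   design is an error, not silently reduced).
#' @param prs_coding `"ordinal"` or `"categorical"`.
#' @param test `"lrt"` (default) or `"wald"`.
#' @return list: p, statistic, df, method, fit_full, fit_null.
#' @export
interaction_test <- function(profiles, cohort, exposure, outcome = "case",
                             covariates = character(),
                             prs_coding = c("ordinal", "categorical"),
                             test = c("lrt", "wald")) {
  prs_coding <- match.arg(prs_coding)
  test <- match.arg(test)
  idx <- match(profiles$subject_id, cohort$subject_id)
  if (anyNA(idx)) stop("profiles contain subjects absent from cohort")
  df <- data.frame(.y = cohort[[outcome]][idx],
                   .e = cohort[[exposure]][idx])
  df$.prs <- if (prs_coding == "ordinal") {
    as.numeric(profiles$category) - 1
  } else {
    factor(profiles$category, ordered = FALSE)
  }
  for (v in covariates) df[[v]] <- cohort[[v]][idx]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  rhs <- paste(c(".prs", ".e", covariates), collapse = " + ")
  null_fit <- stats::glm(stats::as.formula(paste(".y ~", rhs)), data = df,
                         family = stats::binomial(),
                         control = stats::glm.control(epsilon = 1e-8,
                                                      maxit = 50))
  full_fit <- stats::glm(stats::as.formula(paste(".y ~", rhs, "+ .prs:.e")),
                         data = df, family = stats::binomial(),
                         control = stats::glm.control(epsilon = 1e-8,
                                                      maxit = 50))
  if (anyNA(stats::coef(null_fit)) || anyNA(stats::coef(full_fit))) {
    stop("rank-deficient design: a covariate is collinear with the ",
         "exposure or PRS; drop it before testing")
  }
  int_terms <- grep("\\.prs.*:\\.e|\\.e.*:\\.prs",
                    names(stats::coef(full_fit)))
  if (test == "lrt") {
    stat <- as.numeric(2 * (stats::logLik(full_fit) - stats::logLik(null_fit)))
    dfree <- length(int_terms)
    p <- stats::pchisq(stat, dfree, lower.tail = FALSE)
    method <- "likelihood ratio"
  } else {
    co <- summary(full_fit)$coefficients
    b <- co[int_terms, "Estimate"]
    V <- stats::vcov(full_fit)[int_terms, int_terms, drop = FALSE]
    stat <- as.numeric(t(b) %*% solve(V) %*% b)
    dfree <- length(int_terms)
    p <- stats::pchisq(stat, dfree, lower.tail = FALSE)
    method <- "Wald"
  }
  list(p = p, statistic = stat, df = dfree, method = method,
       fit_full = full_fit, fit_null = null_fit)
}
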
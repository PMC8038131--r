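# Per-SNP QC (MAF, Hardy-Weinberg) and covariate-adjusted logistic
# association, then threshold-based candidate selection.

#' Hardy-Weinberg equilibrium test
#'
#' One-df chi-squared goodness-of-fit of the genotype counts against
#' HWE expectations computed from the sample allele frequency. For
#' low-MAF SNPs the Levene-Haldane exact test (summing probabilities of
#' heterozygote counts no more likely than the observed one) is
#' available; `method = "auto"` switches to it when the sample MAF is
#' below 0.05.
#'
#' @param n0,n1,n2 counts of major-homozygote, heterozygote and
#'   minor-homozygote genotypes.
#' @param method `"chisq"`, `"exact"` or `"auto"`.
#' @return the HWE p-value. Monomorphic SNPs return 1 with a warning.
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions -> p = 1
#' hwe_test(10, 10, 10)   # chi2 = 10/3, p ~= 0.068
#' @export
hwe_test <- function(n0, n1, n2, method = c("chisq", "exact", "auto")) {
  method <- match.arg(method)
  stopifnot(n0 >= 0, n1 >= 0, n2 >= 0, n0 + n1 + n2 >= 1)
  n <- n0 + n1 + n2
  q <- (n1 + 2 * n2) / (2 * n)
  if (q == 0 || q == 1) {
    warning("monomorphic SNP: HWE p defined as 1")
    return(1)
  }
  if (method == "auto") method <- if (min(q, 1 - q) < 0.05) "exact" else "chisq"
  if (method == "chisq") {
    expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    chi2 <- sum((c(n0, n1, n2) - expected)^2 / expected)
    return(stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  }
  hwe_exact_p(n0, n1, n2)
}

# Levene-Haldane exact distribution of the heterozygote count given the
# minor-allele count; p = sum of P(het) over counts with P <= P(observed).
hwe_exact_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  n_minor <- n1 + 2 * n2
  if (n_minor > n) { # orient on the rarer allele
    n_minor <- 2 * n - n_minor
    tmp <- n0; n0 <- n2; n2 <- tmp
  }
  hets <- seq.int(n_minor %% 2, n_minor, by = 2)
  # unnormalized log P(het = h | n, n_minor); the h-free factor
  # n_minor! n_major! / (2n)! cancels in the normalization
  log_p <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_min + 1) -
      lgamma(hom_maj + 1) + h * log(2)
  }, numeric(1))
  log_p <- log_p - max(log_p)
  p_all <- exp(log_p) / sum(exp(log_p))
  p_obs <- p_all[match(n1, hets)]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-9)]))
}

#' Minor allele frequency of a genotype column
#'
#' `min(q, 1 - q)` with `q = (n1 + 2 n2) / (2 n)`; missing genotypes are
#' excluded.
#'
#' @param g integer vector of additive genotype codes 0/1/2 (NA allowed).
#' @return frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("no called genotypes")
  q <- sum(g) / (2 * length(g))
  min(q, 1 - q)
}

#' Per-SNP QC statistics
#'
#' @param g a [genotype_matrix()].
#' @param hwe_method passed to [hwe_test()].
#' @return data.frame with snp_id, genotype counts, call_rate, maf and
#'   hwe_p, one row per SNP.
#' @export
snp_qc_stats <- function(g, hwe_method = "chisq") {
  stopifnot(inherits(g, "genotype_matrix"))
  mat <- unclass(g)
  do.call(rbind, lapply(colnames(mat), function(s) {
    x <- mat[, s]
    n0 <- sum(x == 0L, na.rm = TRUE)
    n1 <- sum(x == 1L, na.rm = TRUE)
    n2 <- sum(x == 2L, na.rm = TRUE)
    data.frame(snp_id = s, n0 = n0, n1 = n1, n2 = n2,
               call_rate = (n0 + n1 + n2) / length(x),
               maf = compute_maf(x),
               hwe_p = suppressWarnings(hwe_test(n0, n1, n2,
                                                 method = hwe_method)),
               stringsAsFactors = FALSE)
  }))
}

#' Covariate-adjusted logistic association for one SNP
#'
#' Fits `outcome ~ genotype + covariates` by logistic regression
#' (iteratively reweighted least squares via `glm`) with the SNP coded
#' additively on minor-allele counts (dominant/recessive coding by
#' option), and reports the Wald odds ratio, 95% CI and p-value for the
#' genotype term. With no covariates this equals the classic
#' allelic-trend fit; quasi-separation (|beta| > 15) is flagged as
#' non-converged rather than reported as a finite OR.
#'
#' @param g integer genotype vector 0/1/2.
#' @param outcome binary 0/1 vector.
#' @param covariates optional data.frame of adjustment covariates.
#' @param coding `"additive"` (default), `"dominant"` or `"recessive"`.
#' @return one-row data.frame: or, ci_low, ci_high, p, beta, se,
#'   converged, n.
#' @export
logistic_assoc <- function(g, outcome, covariates = NULL,
                           coding = c("additive", "dominant", "recessive")) {
  coding <- match.arg(coding)
  x <- switch(coding,
              additive = g,
              dominant = as.integer(g >= 1),
              recessive = as.integer(g == 2))
  df <- data.frame(.y = outcome, .g = x)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(outcome))
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  co <- summary(fit)$coefficients
  if (!".g" %in% rownames(co)) {
    stop("genotype term dropped (monomorphic after complete cases?)")
  }
  beta <- co[".g", "Estimate"]
  se <- co[".g", "Std. Error"]
  converged <- fit$converged && abs(beta) <= 15
  data.frame(or = exp(beta),
             ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             p = co[".g", "Pr(>|z|)"],
             beta = beta, se = se,
             converged = converged, n = nrow(df))
}

#' Association screen over all SNPs
#'
#' Runs [snp_qc_stats()] and [logistic_assoc()] for every SNP and
#' returns one table mirroring a GWAS summary: SNP metadata, OR with CI
#' and p, MAF and HWE p.
#'
#' @param g a [genotype_matrix()].
#' @param outcome binary vector aligned to `g` rows.
#' @param covariates optional data.frame of covariates.
#' @param coding genotype coding for [logistic_assoc()].
#' @param hwe_method passed to [hwe_test()].
#' @return data.frame, one row per SNP, ordered as in `g`.
#' @export
association_screen <- function(g, outcome, covariates = NULL,
                               coding = "additive", hwe_method = "chisq") {
  qc <- snp_qc_stats(g, hwe_method = hwe_method)
  eff <- do.call(rbind, lapply(colnames(g), function(s) {
    logistic_assoc(unclass(g)[, s], outcome, covariates, coding = coding)
  }))
  specs <- snp_info(g)
  cbind(specs[match(qc$snp_id, specs$snp_id),
              c("snp_id", "chrom", "position", "minor_allele",
                "major_allele", "gene")],
        eff, qc[, c("maf", "hwe_p", "call_rate")], row.names = NULL)
}

#' Threshold-based candidate selection
#'
#' Keeps SNPs passing all three filters -- association p below
#' `p_threshold`, MAF above `maf_min`, HWE p above `hwe_min` -- sorted
#' by association p. Thresholds are configuration, never hard-coded:
#' the screening p-value in particular is a study choice.
#'
#' @param screen result of [association_screen()] (columns p, maf,
#'   hwe_p).
#' @param p_threshold association p-value cutoff (default 1e-6).
#' @param maf_min minimum MAF (default 0.01, exclusive).
#' @param hwe_min minimum HWE p (default 0.05, exclusive).
#' @return the surviving rows, sorted by `p`.
#' @export
select_candidates <- function(screen, p_threshold = 1e-6, maf_min = 0.01,
                              hwe_min = 0.05) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  keep <- screen$p < p_threshold & screen$maf > maf_min &
    screen$hwe_p > hwe_min
  out <- screen[keep, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}
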
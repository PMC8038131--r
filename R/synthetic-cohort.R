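# Synthetic case-control cohorts with the genetic and environmental
# structure the pipeline assumes: HWE genotypes at specified MAFs,
# optional two-locus LD blocks, a logistic disease model with additive
# per-SNP effects plus cell-level epistatic penetrance increments, and
# lifestyle exposures loosely matched to published cohort marginals.

#' Simulate HWE genotypes
#'
#' Draws an additive-coded genotype matrix. Each SNP is sampled i.i.d.
#' under Hardy-Weinberg proportions ((1-q)^2, 2q(1-q), q^2) for MAF q;
#' SNPs are independent unless an LD block requests haplotype-pair
#' sampling at a given D' (or explicit haplotype frequencies).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param specs a [snp_specs()] table.
#' @param seed integer seed; the call is deterministic given the seed.
#' @param ld_blocks optional list of two-SNP blocks, each a list with
#'   `snps` (two snp_ids from `specs`) and either `d_prime` (signed,
#'   in [-1, 1], relative to the minor alleles) or `hap_freqs` (length-4
#'   numeric, order AB, Ab, aB, ab with A/B the minor alleles).
#' @param missing_rate per-genotype missingness probability.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_subjects, specs, seed,
                               ld_blocks = NULL, missing_rate = 0) {
  stopifnot(n_subjects >= 1)
  if (!inherits(specs, "snp_spec")) {
    specs <- snp_specs(specs$snp_id, specs$chrom, specs$position,
                       specs$minor_allele, specs$major_allele, specs$maf)
  }
  m <- nrow(specs)
  withr::with_seed(seed, {
    g <- matrix(NA_integer_, n_subjects, m,
                dimnames = list(sprintf("S%05d", seq_len(n_subjects)),
                                specs$snp_id))
    in_block <- character()
    for (blk in ld_blocks) {
      ids <- blk$snps
      if (length(ids) != 2 || !all(ids %in% specs$snp_id)) {
        stop("each LD block must name two SNPs present in specs")
      }
      qa <- specs$maf[specs$snp_id == ids[1]]
      qb <- specs$maf[specs$snp_id == ids[2]]
      hf <- if (!is.null(blk$hap_freqs)) {
        stopifnot(length(blk$hap_freqs) == 4,
                  abs(sum(blk$hap_freqs) - 1) < 1e-8,
                  all(blk$hap_freqs >= 0))
        blk$hap_freqs
      } else {
        hap_freqs_from_dprime(qa, qb, blk$d_prime)
      }
      # two haplotypes per subject; genotype = minor-allele count
      h1 <- sample.int(4, n_subjects, replace = TRUE, prob = hf)
      h2 <- sample.int(4, n_subjects, replace = TRUE, prob = hf)
      a_count <- (h1 <= 2) + (h2 <= 2)          # haps AB, Ab carry A
      b_count <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))  # AB, aB carry B
      g[, ids[1]] <- as.integer(a_count)
      g[, ids[2]] <- as.integer(b_count)
      in_block <- c(in_block, ids)
    }
    for (j in setdiff(specs$snp_id, in_block)) {
      q <- specs$maf[specs$snp_id == j]
      g[, j] <- stats::rbinom(n_subjects, 2L, q)
    }
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(n_subjects * m) < missing_rate,
                     n_subjects, m)
      g[drop] <- NA_integer_
    }
    genotype_matrix(g, specs)
  })
}

#' Haplotype frequencies from allele frequencies and D'
#'
#' Converts a signed D' (relative to the two minor alleles A, B) into
#' the four haplotype frequencies (AB, Ab, aB, ab).
#'
#' @param qa,qb minor allele frequencies at the two loci.
#' @param d_prime signed normalized disequilibrium in [-1, 1].
#' @return numeric length-4 vector, names AB, Ab, aB, ab.
#' @export
hap_freqs_from_dprime <- function(qa, qb, d_prime) {
  stopifnot(d_prime >= -1, d_prime <= 1)
  dmax <- if (d_prime >= 0) {
    min(qa * (1 - qb), (1 - qa) * qb)
  } else {
    min(qa * qb, (1 - qa) * (1 - qb))
  }
  d <- d_prime * dmax
  hf <- c(AB = qa * qb + d, Ab = qa * (1 - qb) - d,
          aB = (1 - qa) * qb - d, ab = (1 - qa) * (1 - qb) + d)
  stopifnot(all(hf >= -1e-12))
  pmax(hf, 0)
}

#' Disease model specification
#'
#' A logistic penetrance model: log-odds are an intercept (calibrated
#' to a target prevalence) plus additive per-SNP terms on minor-allele
#' counts, optional two-locus epistatic increments on specific genotype
#' cells, and linear covariate terms.
#'
#' @param snp_log_or named numeric, per-minor-allele log odds ratios.
#' @param epistasis_terms list of terms from [epistasis_cells()].
#' @param covariate_log_or named numeric, per-unit log odds ratios for
#'   cohort columns.
#' @param prevalence_target overall case proportion in (0, 1).
#' @return list of class `disease_model`.
#' @export
disease_model <- function(snp_log_or = numeric(), epistasis_terms = list(),
                          covariate_log_or = numeric(),
                          prevalence_target = 0.009) {
  stopifnot(all(is.finite(snp_log_or)), all(is.finite(covariate_log_or)),
            prevalence_target > 0, prevalence_target < 1)
  for (term in epistasis_terms) {
    stopifnot(length(term$snps) == 2, is.matrix(term$cells),
              all(dim(term$cells) == c(3, 3)), all(is.finite(term$cells)))
  }
  structure(list(snp_log_or = snp_log_or,
                 epistasis_terms = epistasis_terms,
                 covariate_log_or = covariate_log_or,
                 prevalence_target = prevalence_target),
            class = "disease_model")
}

#' Two-locus epistatic penetrance increments
#'
#' Encodes epistasis as log-odds increments on specific two-locus
#' genotype cells (rows = genotype 0/1/2 at the first SNP, columns at
#' the second), the cell-pattern form that MDR-type methods detect.
#' `xor_epistasis()` builds the classic checkerboard pattern (cells with
#' an odd genotype sum get the increment), which carries essentially no
#' marginal single-SNP effect.
#'
#' @param snp_a,snp_b snp ids.
#' @param cells 3x3 numeric matrix of log-odds increments.
#' @return a list usable in `epistasis_terms` of [disease_model()].
#' @export
epistasis_cells <- function(snp_a, snp_b, cells) {
  stopifnot(is.matrix(cells), all(dim(cells) == c(3, 3)))
  list(snps = c(snp_a, snp_b), cells = cells)
}

#' @rdname epistasis_cells
#' @param effect log-odds increment applied to checkerboard cells.
#' @export
xor_epistasis <- function(snp_a, snp_b, effect = 1.0) {
  cells <- outer(0:2, 0:2, function(i, j) ifelse((i + j) %% 2 == 1, effect, 0))
  epistasis_cells(snp_a, snp_b, cells)
}

model_linear_predictor <- function(g, cohort, model) {
  eta <- numeric(nrow(g))
  for (s in names(model$snp_log_or)) {
    if (!s %in% colnames(g)) stop("disease model references absent SNP: ", s)
    eta <- eta + model$snp_log_or[[s]] * unclass(g)[, s]
  }
  for (term in model$epistasis_terms) {
    if (!all(term$snps %in% colnames(g))) {
      stop("epistasis term references absent SNP(s): ",
           paste(setdiff(term$snps, colnames(g)), collapse = ", "))
    }
    ga <- unclass(g)[, term$snps[1]]
    gb <- unclass(g)[, term$snps[2]]
    eta <- eta + term$cells[cbind(ga + 1L, gb + 1L)]
  }
  for (v in names(model$covariate_log_or)) {
    if (is.null(cohort) || !v %in% names(cohort)) {
      stop("disease model references absent covariate: ", v)
    }
    x <- cohort[[v]]
    if (is.factor(x) || is.character(x)) {
      stop("covariate '", v, "' must be numeric in the disease model")
    }
    eta <- eta + model$covariate_log_or[[v]] * x
  }
  eta
}

#' Simulate the case-control outcome
#'
#' Attaches a Bernoulli outcome drawn from the logistic disease model.
#' The intercept is auto-calibrated by bisection (50 iterations,
#' prevalence tolerance 1e-4) so the expected case fraction matches
#' `model$prevalence_target`.
#'
#' @param g a [genotype_matrix()].
#' @param model a [disease_model()].
#' @param seed integer seed.
#' @param cohort optional data.frame of covariates/exposures, one row
#'   per subject in `g`'s row order (a `subject_id` column is added if
#'   absent).
#' @return `cohort` (or a fresh table) with `subject_id` and a binary
#'   `case` column; the calibrated intercept is attached as attribute
#'   `intercept`.
#' @export
simulate_outcome <- function(g, model, seed, cohort = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(model, "disease_model"))
  n <- nrow(g)
  if (is.null(cohort)) {
    cohort <- data.frame(subject_id = rownames(g), stringsAsFactors = FALSE)
  } else {
    stopifnot(nrow(cohort) == n)
    if (!"subject_id" %in% names(cohort)) cohort$subject_id <- rownames(g)
  }
  eta <- model_linear_predictor(g, cohort, model)
  intercept <- calibrate_intercept(eta, model$prevalence_target)
  withr::with_seed(seed, {
    p <- stats::plogis(intercept + eta)
    cohort$case <- stats::rbinom(n, 1L, p)
  })
  attr(cohort, "intercept") <- intercept
  cohort
}

calibrate_intercept <- function(eta, target, max_iter = 50, tol = 1e-4) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) stop("prevalence target unresolvable")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (abs(f(mid)) < tol) return(mid)
  }
  mid <- (lo + hi) / 2
  if (abs(f(mid)) >= tol) stop("prevalence calibration did not converge")
  mid
}

#' Exposure specification
#'
#' Declares one lifestyle/clinical exposure for the generator: a
#' truncated-normal continuous variable or a categorical one, with the
#' cutoff later used to dichotomize it into low/high.
#'
#' @param name column name.
#' @param kind `"continuous"` or `"categorical"`.
#' @param mean,sd,lower normal parameters and truncation bound
#'   (continuous kind).
#' @param levels,probs level labels and probabilities (categorical kind).
#' @param cutoff dichotomization cutoff; must lie inside the support.
#' @param case_shift optional additive shift of the mean (continuous) in
#'   cases, emulating outcome-dependent exposure (e.g. post-diagnosis
#'   behaviour change); applied only when the generator is given the
#'   outcome.
#' @return list of class `exposure_spec`.
#' @export
exposure_spec <- function(name, kind = c("continuous", "categorical"),
                          mean = 0, sd = 1, lower = -Inf,
                          levels = NULL, probs = NULL, cutoff = NA_real_,
                          case_shift = 0) {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    stopifnot(sd > 0)
    if (!is.na(cutoff) && cutoff < lower) {
      stop("cutoff for '", name, "' lies below the truncation bound")
    }
  } else {
    stopifnot(!is.null(levels), !is.null(probs),
              length(levels) == length(probs), abs(sum(probs) - 1) < 1e-8)
  }
  structure(list(name = name, kind = kind, mean = mean, sd = sd,
                 lower = lower, levels = levels, probs = probs,
                 cutoff = cutoff, case_shift = case_shift),
            class = "exposure_spec")
}

#' Default exposure panel
#'
#' Continuous and categorical lifestyle variables loosely matched to the
#' marginals of a Korean middle-aged hospital cohort: gender, age, BMI,
#' white blood cell count (10^9/L, cutoff 4), energy intake as percent
#' of the estimated energy requirement (cutoff 100), alcohol (g/day,
#' cutoff 20) and seaweed (g/day, cutoff 2.65) intakes.
#'
#' @return list of [exposure_spec()] objects.
#' @export
default_exposure_specs <- function() {
  list(
    exposure_spec("gender", "categorical", levels = c("man", "woman"),
                  probs = c(0.349, 0.651)),
    exposure_spec("age", "continuous", mean = 53.6, sd = 8, lower = 40,
                  cutoff = 55),
    exposure_spec("bmi", "continuous", mean = 23.9, sd = 3, lower = 14,
                  cutoff = 25),
    exposure_spec("wbc", "continuous", mean = 5.71, sd = 1.5, lower = 0,
                  cutoff = 4),
    exposure_spec("energy_pct", "continuous", mean = 96.1, sd = 25,
                  lower = 0, cutoff = 100),
    exposure_spec("alcohol_g", "continuous", mean = 12, sd = 15, lower = 0,
                  cutoff = 20),
    exposure_spec("seaweed_g", "continuous", mean = 2.2, sd = 1.5, lower = 0,
                  cutoff = 2.65)
  )
}

#' Simulate lifestyle exposures
#'
#' Draws exposure columns from their declared distributions. By default
#' exposures are independent of the outcome; passing `outcome` together
#' with `outcome_dependent = TRUE` applies each spec's `case_shift`
#' (continuous kinds only), emulating post-diagnosis behaviour change.
#'
#' @param n_subjects number of subjects.
#' @param specs list of [exposure_spec()].
#' @param seed integer seed.
#' @param outcome optional binary vector of length `n_subjects`.
#' @param outcome_dependent apply `case_shift` to cases?
#' @return data.frame of exposure columns.
#' @export
simulate_exposures <- function(n_subjects, specs = default_exposure_specs(),
                               seed = 1L, outcome = NULL,
                               outcome_dependent = FALSE) {
  withr::with_seed(seed, {
    out <- list()
    for (sp in specs) {
      if (!inherits(sp, "exposure_spec") ||
            !identical(sp$kind %in% c("continuous", "categorical"), TRUE)) {
        stop("unknown exposure kind",
             if (!is.null(sp$kind)) paste0(": ", sp$kind))
      }
      if (sp$kind == "continuous") {
        x <- rnorm_trunc(n_subjects, sp$mean, sp$sd, sp$lower)
        if (outcome_dependent && !is.null(outcome) && sp$case_shift != 0) {
          shift_idx <- outcome == 1
          x[shift_idx] <- pmax(sp$lower,
                               x[shift_idx] + sp$case_shift)
        }
        out[[sp$name]] <- x
      } else {
        out[[sp$name]] <- factor(
          sample(sp$levels, n_subjects, replace = TRUE, prob = sp$probs),
          levels = sp$levels)
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
}

# one-sided truncated normal by inverse-CDF sampling
rnorm_trunc <- function(n, mean, sd, lower) {
  if (!is.finite(lower)) return(stats::rnorm(n, mean, sd))
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate food-group intakes with latent dietary patterns
#'
#' Generates standardized intakes for `n_groups` food groups where the
#' first `sum(block_sizes)` columns form correlated blocks (a one-factor
#' model per block with loading `sqrt(rho)`), emulating distinct dietary
#' patterns; remaining columns are independent noise. Block membership
#' is recorded in attribute `blocks` so factor-recovery tests can match
#' factors to blocks without name matching.
#'
#' @param n_subjects number of subjects.
#' @param n_groups total food-group columns (default 29).
#' @param block_sizes sizes of the correlated blocks (default four
#'   blocks, emulating four dietary patterns).
#' @param rho within-block correlation (default 0.6).
#' @param seed integer seed.
#' @return numeric matrix with `food_01..` columns and attribute
#'   `blocks` (list of column-index vectors).
#' @export
simulate_food_groups <- function(n_subjects, n_groups = 29,
                                 block_sizes = c(6, 5, 5, 5), rho = 0.6,
                                 seed = 1L) {
  stopifnot(sum(block_sizes) <= n_groups, rho > 0, rho < 1)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n_subjects * n_groups), n_subjects, n_groups)
    colnames(x) <- sprintf("food_%02d", seq_len(n_groups))
    blocks <- list()
    col <- 1L
    for (b in seq_along(block_sizes)) {
      idx <- col:(col + block_sizes[b] - 1L)
      f <- stats::rnorm(n_subjects)
      x[, idx] <- sqrt(rho) * f + sqrt(1 - rho) * x[, idx]
      blocks[[b]] <- idx
      col <- col + block_sizes[b]
    }
    attr(x, "blocks") <- blocks
    x
  })
}
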
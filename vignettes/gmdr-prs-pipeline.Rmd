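---
title: "Building an interaction-aware polygenic risk score with GMDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building an interaction-aware polygenic risk score with GMDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmdrprs)
```

## The problem and the procedure

Thyroid cancer risk is shaped by common variants of individually small
effect whose joint (epistatic) behaviour is invisible to single-SNP
association testing. The pipeline in this package builds a polygenic
risk score (PRS) that is aware of gene–gene interaction, and then asks
whether lifestyle exposures modify the risk carried by that score. The
stages are:

1. **Association screen.** Per-SNP quality control (minor allele
   frequency, Hardy–Weinberg equilibrium) and a covariate-adjusted
   logistic fit of the additively coded minor-allele count; SNPs pass
   on association p, MAF and HWE p thresholds.
2. **LD pruning.** Two-locus haplotype frequencies for same-chromosome
   candidate pairs are estimated by EM from unphased genotypes; of any
   pair with |D′| ≥ 0.4 the SNP with the weaker association is dropped,
   because the pair carries near-duplicate information.
3. **GMDR model search.** Generalized multifactor dimensionality
   reduction evaluates every k-SNP subset of the pruned candidates.
   Subjects are scored by the response residual $s_i = y_i - \hat p_i$
   of a covariate-only null logistic model; each multilocus genotype
   cell is pooled as high risk when its score sum exceeds 0. Ten-fold
   stratified cross-validation yields a trained and a testing balanced
   accuracy (TRBA/TEBA), the number of folds whose test BA exceeds 0.5
   feeds a binomial sign test, and cross-validation consistency (CVC)
   counts folds whose training-best subset equals the overall best.
4. **PRS.** The best model's SNPs each contribute their risk-allele
   count 0/1/2, where the risk allele is the one whose carriage raises
   disease odds (it can be the major allele). The unweighted sum is
   banded into low/medium/high tertile categories and medium/high are
   compared with low in an adjusted logistic model.
5. **Gene–environment interaction.** Exposures are dichotomized at
   preset clinical cutoffs (or at the 70th percentile for dietary
   pattern scores), PRS-category odds ratios are estimated within each
   exposure stratum, and the PRS × exposure interaction is tested by
   likelihood ratio against the main-effects model.
6. **Dietary patterns.** Food-group intakes are reduced by
   principal-component factoring of their correlation matrix
   (eigenvalue > 1.5 retained), varimax-rotated, scored by the
   regression method, and dichotomized at the 70th percentile.

The original cohort behind this design is not publicly deposited, so
the package ships a synthetic-cohort generator that reproduces the
*statistical structure* the pipeline assumes, and every stage is
validated against that generator plus closed-form oracles.

## The synthetic cohort: what it emulates, and what it does not

`simulate_study()` draws, by default:

* **Genotypes** for the ten-SNP cell-growth/inflammation panel
  (`thyroid_snp_panel()`) at the published minor allele frequencies
  (0.020–0.378) under exact Hardy–Weinberg proportions, SNPs
  independent unless a two-SNP LD block with a target D′ is requested
  (haplotype-pair sampling).
* **Disease** from a logistic penetrance model: additive per-SNP
  log-odds at the published odds ratios (0.76–1.94), plus a planted
  two-locus "checkerboard" interaction (+0.8 log-odds on cells with an
  odd genotype sum, rs7834206 × rs72616195 by default). The intercept
  is calibrated by bisection (50 iterations, tolerance 1e-4 in
  prevalence) to a target case fraction of 0.9%, matching a cohort of
  495 cases among 56,934 subjects. Epistasis is encoded as
  cell-penetrance increments rather than product terms because
  MDR-type methods detect cell patterns; the checkerboard carries
  essentially no marginal effect, which makes the recovery experiment
  well-posed.
* **Exposures** from truncated normals / categorical draws loosely
  matched to the published cohort marginals (WBC mean 5.71 × 10⁹/L,
  energy ≈ 96% of the estimated requirement, 65% women, and so on).
  Exposures are independent of the outcome unless `outcome_dependent`
  is set, which applies a per-spec `case_shift` to emulate
  post-diagnosis behaviour change.
* **Food groups**: 29 standardized columns of which four blocks
  (6/5/5/5 variables, within-block correlation 0.6) carry latent
  dietary patterns; the rest are noise. Block membership is recorded
  so factor-recovery tests can match factors to blocks without naming
  them.

What the generator does **not** emulate: genome-scale marker panels
(the screen is exercised at tens of SNPs), population stratification
and relatedness, genotyping error and informative missingness,
covariance between lifestyle exposures, and the original cohort's
joint exposure distribution beyond its published marginals. Passing
tests therefore demonstrate that the machinery is correct and
calibrated under the assumed structure — not that the published
cohort-specific effect estimates (e.g. a 3.9-fold high-PRS odds ratio)
are recoverable; those depend on the inaccessible data and are covered
by parameter-recovery properties instead.

## Parameters that matter

| Parameter | Default | Units / rationale |
|---|---|---|
| screen `p_threshold` | 1e-6 (package), 0.05 (desk-scale scripts) | the genome-wide criterion is meaningless at ten SNPs, so the threshold is configuration, never hard-coded |
| `maf_min` | 0.01 | exclusive; keeps rare-but-usable SNPs (MAF 0.02) |
| `hwe_min` | 0.05 | QC inclusion on the HWE goodness-of-fit p |
| LD `threshold` | 0.4 | |D′| at/above which a pair is "strong LD" |
| GMDR `threshold` (T) | 0 | cell score-sum cutoff; ties and empty cells go low |
| `n_folds` | 10 | cross-validation; folds stratified by outcome |
| PRS bands | 0–3/4–6/≥7 (6 SNPs), 0–3/4–5/≥6 (5 SNPs) | shipped presets; empirical tertiles otherwise |
| pattern retention | eigenvalue > 1.5 | principal-component factoring |
| loading significance | \|loading\| ≥ 0.40 | reporting mask only |
| pattern cutoff | 70th percentile | "high" includes the cutoff |
| exposure cutoffs | WBC 4 × 10⁹/L, energy 100% of EER, alcohol 20 g/day, seaweed 2.65 g/day | boundary value is "high" (≥ rule) |

## Numerical choices

* **Logistic fits** use `stats::glm` (iteratively reweighted least
  squares) with deviance tolerance 1e-8 and 50 iterations. Wald 95%
  CIs are `exp(β ± 1.96·SE)`, matching the reporting style of the
  field. Quasi-separation is flagged when |β| > 15 and the estimate is
  marked non-converged rather than reported as a finite OR.
* **HWE**: one-df chi-squared against expectations from the sample
  allele frequency; a hand-written Levene–Haldane exact test is used
  for MAF < 0.05 under `method = "auto"`. Monomorphic SNPs return p = 1
  with a warning.
* **EM** for two-locus haplotypes iterates the double-heterozygote
  split to a frequency change below 1e-10 (max 200 iterations); the
  observed-data log-likelihood is tracked and is non-decreasing.
* **Fold construction** is keyed to sorted subject ids plus the seed,
  never to row order, so permuting subjects changes nothing.
* **Tie-breaks** in the model search: best = highest mean TEBA, then
  higher CVC, then lexicographic subset order.
* **Degenerate inputs** error loudly: folds smaller than a class,
  monomorphic loci, all-one-side exposures, rank-deficient interaction
  designs, an OR of exactly 1 at risk-allele orientation.
* All randomness flows from explicit seeds through `withr::with_seed`;
  nothing depends on the global RNG state.

## Design decisions where the design was open

* **Per-SNP genotype coding** for the screen is additive by default
  (dominant/recessive available) — the convention when the choice is
  unstated.
* **Sign test**: the printed model-selection p-values (0.0010, 0.0107,
  0.0547, 0.1719, 0.3770 for 10..6 fold wins) equal binomial(10, ½)
  upper tails exactly, so the test is implemented as that closed form.
* **Search strategy**: exhaustive per k is the default; a forward
  (nested) strategy is provided because published best-model sequences
  are often nested, and the two can disagree — the package does not
  adjudicate which produced any given published table.
* **Selection inflates the sign test.** The sign test is exact for a
  *pre-specified* SNP combination; applied to the best of C(m, k)
  subsets it is anti-conservative. The calibration property we assert
  is therefore for a fixed combination under the null (rejection rate
  at most nominal); the selected-model p-values are reported as
  descriptive statistics, as is conventional for MDR-family software.
* **LD pruning** keeps the most significant SNP of a high-LD pair
  (the drop rule is unstated in the field's reports); removals are
  logged so the candidate bookkeeping is auditable.
* **Missing genotypes** exclude a subject from the PRS by default;
  rounded-mean imputation is opt-in and logged.
* **Alcohol as exposure**: the interaction machinery drops any
  adjustment covariate that collides with the tested exposure; how the
  original analysis avoided that collision is unstated.
* **Weighting**: the PRS is an unweighted allele count by design;
  β-weighted scores are out of scope for the shipped pipeline.

## Problem sizes used by the tests

The suite exercises: HWE/association calibration at n = 250–400 over
300–600 seeds; EM recovery at n = 10,000; planted-pair recovery over
50 replicates of n = 5,000 at cell effect +1.0 and case fraction 0.2
(a case-enriched design, chosen because a 0.9% prevalence at n = 5,000
leaves ~45 cases — too few for any cell-based method); GMDR–classic-MDR
equivalence exhaustively on instances up to 3 SNPs × 60 subjects;
PRS dose–response at n = 6,000 over 40 replicates against an
infinite-data analytic target; interaction-null uniformity at n = 1,000
over 500 seeds. The analysis scripts run the full cohort size
(n = 56,934), where the exhaustive k ≤ 6 search over ten candidates
takes about a minute.

## Known limitations

* No population-structure correction (genomic control, principal
  components) and no imputation: the screen assumes a homogeneous
  cohort, as the generator produces.
* The exhaustive search is limited to candidate sets around 15 SNPs by
  combinatorics.
* Empirical tertiles on small integer score ranges can collapse; the
  bander then widens to the nearest non-degenerate integer bands.
* Stratified interaction ORs require every stratum × category cell to
  have both outcomes; sparse cells are reported non-estimable rather
  than silently dropped.
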
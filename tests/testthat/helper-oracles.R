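# Independent oracles and small fixture builders used across the suite.

# Classic MDR on raw counts: a cell is high risk iff its case:control
# ratio exceeds the overall case:control ratio of the training data
# (controls absent with cases present counts as high; empty cells low).
# Returns the high/low labels over all 3^k cells plus balanced accuracy
# computed directly from counts. Written from scratch on purpose: it
# shares no code with the GMDR engine.
oracle_mdr <- function(gmat, y, combo) {
  k <- length(combo)
  n_cells <- 3^k
  idx <- rep(1, nrow(gmat))
  mult <- 1
  for (j in seq_len(k)) {
    idx <- idx + gmat[, combo[j]] * mult
    mult <- mult * 3
  }
  cases <- ctrls <- numeric(n_cells)
  for (c in seq_len(n_cells)) {
    cases[c] <- sum(y == 1 & idx == c)
    ctrls[c] <- sum(y == 0 & idx == c)
  }
  thr <- sum(y == 1) / sum(y == 0)
  high <- ifelse(ctrls > 0, cases / ctrls > thr, cases > 0)
  pred <- high[idx]
  sens <- sum(pred & y == 1) / sum(y == 1)
  spec <- sum(!pred & y == 0) / sum(y == 0)
  list(high = high, ba = (sens + spec) / 2)
}

# balanced 1:1 case-control toy instance with k SNPs; returns a
# genotype_matrix and outcome vector
balanced_toy <- function(n_per_class, k, seed) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    mat <- matrix(sample(0:2, n * k, replace = TRUE), n, k,
                  dimnames = list(sprintf("S%03d", 1:n),
                                  paste0("snp", 1:k)))
    y <- rep(c(0L, 1L), each = n_per_class)[sample.int(n)]
    specs <- snp_specs(paste0("snp", 1:k), chrom = rep("1", k),
                       position = seq_len(k) * 1000L,
                       minor_allele = rep("A", k),
                       major_allele = rep("G", k),
                       maf = rep(0.3, k))
    list(g = genotype_matrix(mat, specs), y = y)
  })
}

# simple spec table for generator tests
toy_specs <- function(mafs, chrom = NULL) {
  m <- length(mafs)
  snp_specs(paste0("snp", seq_len(m)),
            chrom = if (is.null(chrom)) rep("1", m) else chrom,
            position = seq_len(m) * 1000L,
            minor_allele = rep("A", m), major_allele = rep("G", m),
            maf = mafs)
}

# draw unphased genotypes for n subjects from explicit haplotype
# frequencies (AB, Ab, aB, ab); independent of the package generator
draw_from_haps <- function(n, hf, seed) {
  withr::with_seed(seed, {
    h1 <- sample.int(4, n, replace = TRUE, prob = hf)
    h2 <- sample.int(4, n, replace = TRUE, prob = hf)
    list(ga = (h1 <= 2) + (h2 <= 2),
         gb = (h1 %in% c(1, 3)) + (h2 %in% c(1, 3)))
  })
}

# direct D' from a frequency vector, written out independently
direct_dprime <- function(hap) {
  fA <- hap[1] + hap[2]; fB <- hap[1] + hap[3]
  d <- hap[1] - fA * fB
  dmax <- if (d > 0) min(fA * (1 - fB), (1 - fA) * fB)
          else min(fA * fB, (1 - fA) * (1 - fB))
  if (dmax <= 0) return(0)
  abs(d) / dmax
}
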
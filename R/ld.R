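# Two-locus linkage disequilibrium from unphased genotypes: haplotype
# frequencies by EM (only the double heterozygote is phase-ambiguous),
# D' and r2, and greedy within-chromosome pruning of high-LD pairs.

#' EM haplotype frequencies for a SNP pair
#'
#' Maximum-likelihood haplotype frequencies (AB, Ab, aB, ab, with A/B
#' the minor alleles) from unphased two-locus genotypes. All genotype
#' classes except the double heterozygote determine their haplotypes;
#' the EM splits the double heterozygotes between the cis (AB/ab) and
#' trans (Ab/aB) phases at each step. Iterated until the largest
#' frequency change is below `tol` (default 1e-10) or `max_iter`.
#'
#' @param ga,gb integer genotype vectors 0/1/2 (minor-allele counts);
#'   subjects with a missing value at either locus are dropped.
#' @param tol,max_iter EM stopping rule.
#' @return list of class `ld_result`: `hap` (named length-4 frequency
#'   vector), `d`, `d_prime`, `r2`, `loglik` (per-iteration trace),
#'   `n_iter`, `n` (doubly-called subjects).
#' @export
em_haplotypes <- function(ga, gb, tol = 1e-10, max_iter = 200) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  if (length(ga) == 0) stop("no doubly-called subjects")
  counts <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) counts[i + 1, j + 1] <- sum(ga == i & gb == j)
  n <- sum(counts)
  qa <- sum(ga) / (2 * n); qb <- sum(gb) / (2 * n)
  if (qa %in% c(0, 1) || qb %in% c(0, 1)) {
    warning("monomorphic locus: D' defined as 0")
    hap <- c(AB = qa * qb, Ab = qa * (1 - qb),
             aB = (1 - qa) * qb, ab = (1 - qa) * (1 - qb))
    return(structure(list(hap = hap, d = 0, d_prime = 0, r2 = 0,
                          loglik = NA_real_, n_iter = 0L, n = n),
                     class = "ld_result"))
  }
  # fixed haplotype contributions from unambiguous genotype cells;
  # genotype (i, j) carries haplotypes with i copies of A, j of B
  fixed <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  add <- function(f, h, k) { f[h] <- f[h] + k; f }
  for (i in 0:2) for (j in 0:2) {
    k <- counts[i + 1, j + 1]
    if (k == 0 || (i == 1 && j == 1)) next
    # phase is determined: split the two haplotypes per subject
    h1 <- paste0(ifelse(i >= 1, "A", "a"), ifelse(j >= 1, "B", "b"))
    h2 <- paste0(ifelse(i == 2, "A", "a"), ifelse(j == 2, "B", "b"))
    fixed <- add(fixed, h1, k)
    fixed <- add(fixed, h2, k)
  }
  n_dh <- counts[2, 2]
  hap <- c(AB = qa * qb, Ab = qa * (1 - qb),
           aB = (1 - qa) * qb, ab = (1 - qa) * (1 - qb))
  loglik <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cis <- hap["AB"] * hap["ab"]
    trans <- hap["Ab"] * hap["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new_counts <- fixed +
      c(AB = w, Ab = 1 - w, aB = 1 - w, ab = w) * n_dh
    new_hap <- new_counts / (2 * n)
    loglik <- c(loglik, em_loglik(counts, new_hap))
    delta <- max(abs(new_hap - hap))
    hap <- new_hap
    if (delta < tol || iter >= max_iter) break
  }
  d <- unname(hap["AB"] - qa * qb)
  structure(list(hap = hap, d = d, d_prime = dprime(hap),
                 r2 = d^2 / (qa * (1 - qa) * qb * (1 - qb)),
                 loglik = loglik, n_iter = iter, n = n),
            class = "ld_result")
}

# observed-data log-likelihood of the genotype table under hap freqs
em_loglik <- function(counts, hap) {
  ll <- 0
  for (i in 0:2) for (j in 0:2) {
    k <- counts[i + 1, j + 1]
    if (k == 0) next
    p <- genotype_prob_from_haps(hap, i, j)
    ll <- ll + k * log(max(p, 1e-300))
  }
  ll
}

# P(genotype pair (i, j)) from random union of two haplotypes
genotype_prob_from_haps <- function(hap, i, j) {
  haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0)) # A,B content of AB,Ab,aB,ab
  p <- 0
  for (u in 1:4) for (v in 1:4) {
    if (haps[u, 1] + haps[v, 1] == i && haps[u, 2] + haps[v, 2] == j) {
      p <- p + hap[u] * hap[v]
    }
  }
  unname(p)
}

#' Normalized disequilibrium D'
#'
#' `D = f(AB) - f(A) f(B)`; `D' = |D| / Dmax` where `Dmax` is
#' `min(f(A) f(b), f(a) f(B))` for positive D and
#' `min(f(A) f(B), f(a) f(b))` for negative D. The sign is discarded
#' (|D'| reported, as in conventional Haploview output).
#'
#' @param hap length-4 frequency vector (AB, Ab, aB, ab) summing to 1.
#' @return |D'| in `[0, 1]`. A monomorphic margin gives 0 with a warning.
#' @export
dprime <- function(hap) {
  stopifnot(length(hap) == 4, all(hap >= -1e-12),
            abs(sum(hap) - 1) < 1e-6)
  fA <- hap[1] + hap[2]; fB <- hap[1] + hap[3]
  fa <- 1 - fA; fb <- 1 - fB
  if (fA <= 0 || fa <= 0 || fB <= 0 || fb <= 0) {
    warning("allele frequency 0: D' defined as 0")
    return(0)
  }
  d <- hap[1] - fA * fB
  dmax <- if (d > 0) min(fA * fb, fa * fB) else min(fA * fB, fa * fb)
  if (dmax <= 0) return(0)
  unname(abs(d) / dmax)
}

#' Pairwise within-chromosome LD table
#'
#' @param g a [genotype_matrix()].
#' @param snp_ids SNPs to test (default all in `g`).
#' @return data.frame of pairwise `ld_result` rows (snp_a, snp_b,
#'   chrom, hap freqs, d, d_prime, r2), same-chromosome pairs only;
#'   cross-chromosome pairs are never tested.
#' @export
ld_table <- function(g, snp_ids = colnames(g)) {
  specs <- snp_info(g)
  specs <- specs[specs$snp_id %in% snp_ids, , drop = FALSE]
  rows <- list()
  for (chr in unique(specs$chrom)) {
    ids <- specs$snp_id[specs$chrom == chr]
    if (length(ids) < 2) next
    for (a in seq_len(length(ids) - 1)) for (b in (a + 1):length(ids)) {
      r <- suppressWarnings(
        em_haplotypes(unclass(g)[, ids[a]], unclass(g)[, ids[b]]))
      rows[[length(rows) + 1]] <- data.frame(
        snp_a = ids[a], snp_b = ids[b], chrom = chr,
        f_AB = unname(r$hap[1]), f_Ab = unname(r$hap[2]),
        f_aB = unname(r$hap[3]), f_ab = unname(r$hap[4]),
        d = r$d, d_prime = r$d_prime, r2 = r$r2,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(snp_a = character(), snp_b = character(),
                      chrom = character(), d = numeric(),
                      d_prime = numeric(), r2 = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Greedy LD pruning of a candidate list
#'
#' Within each chromosome, SNP pairs with D' at or above `threshold`
#' are resolved by repeatedly dropping the SNP with the largest
#' association p-value among the flagged pairs, so the result does not
#' depend on input order when p-values are distinct. Every removal is
#' logged with its partner and D'.
#'
#' @param g a [genotype_matrix()].
#' @param candidates data.frame with columns `snp_id` and `p` (e.g. from
#'   [select_candidates()]).
#' @param threshold D' at/above which a pair is "strong LD" (default 0.4).
#' @return list: `kept` (snp ids), `removed` (log data.frame with
#'   snp_id, partner, d_prime, p), `ld` (the pairwise table).
#' @export
prune_by_ld <- function(g, candidates, threshold = 0.4) {
  stopifnot(all(c("snp_id", "p") %in% names(candidates)))
  ld <- ld_table(g, candidates$snp_id)
  pval <- stats::setNames(candidates$p, candidates$snp_id)
  alive <- candidates$snp_id
  removed <- list()
  repeat {
    hot <- ld[ld$d_prime >= threshold &
                ld$snp_a %in% alive & ld$snp_b %in% alive, , drop = FALSE]
    if (nrow(hot) == 0) break
    involved <- unique(c(hot$snp_a, hot$snp_b))
    worst <- involved[which.max(pval[involved])]
    pair <- hot[hot$snp_a == worst | hot$snp_b == worst, , drop = FALSE]
    pair <- pair[which.max(pair$d_prime), ]
    partner <- setdiff(c(pair$snp_a, pair$snp_b), worst)
    removed[[length(removed) + 1]] <- data.frame(
      snp_id = worst, partner = partner, d_prime = pair$d_prime,
      p = unname(pval[worst]), stringsAsFactors = FALSE)
    alive <- setdiff(alive, worst)
  }
  list(kept = alive,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(snp_id = character(), partner = character(),
                    d_prime = numeric(), p = numeric()),
       ld = ld)
}
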
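#!/usr/bin/env Rscript
# Stage 2: per-SNP QC and covariate-adjusted logistic association.
#
# Mirrors a GWAS summary at desk scale: minor allele frequency, HWE
# p-value, and the adjusted additive odds ratio per SNP; then applies
# the three screening filters. At ten SNPs the genome-wide p < 1e-6
# threshold is meaningless, so the screen threshold here is 0.05; the
# QC filters (MAF > 0.01, HWE p > 0.05) keep their published values.

library(gmdrprs)

in_dir <- "results/cohort"
specs_df <- read.delim(file.path(in_dir, "snp_specs.tsv"),
                       colClasses = list(chrom = "character"))
specs <- snp_specs(specs_df$snp_id, specs_df$chrom, specs_df$position,
                   specs_df$minor_allele, specs_df$major_allele,
                   specs_df$maf, gene = specs_df$gene)
g <- read_genotypes(file.path(in_dir, "genotypes.tsv"), specs)
cohort <- read_cohort(file.path(in_dir, "cohort.tsv"), genotypes = g)

screen <- association_screen(g, cohort$case,
                             cohort[, c("age", "gender", "bmi")])
write.table(format(screen, digits = 4),
            "results/association_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cand <- select_candidates(screen, p_threshold = 0.05)
write.table(cand["snp_id"], "results/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("screened %d SNPs; %d pass QC + association filters:",
                nrow(screen), nrow(cand)))
message(paste(sprintf("  %s p=%.2e OR=%.2f MAF=%.3f HWEp=%.2f",
                      cand$snp_id, cand$p, cand$or, cand$maf, cand$hwe_p),
              collapse = "\n"))
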
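#!/usr/bin/env Rscript
# Stage 1: generate the synthetic case-control cohort.
#
# Emulates the statistical structure of a large hospital-based
# case-control study of thyroid cancer: 56,934 subjects, the ten-SNP
# cell-growth/inflammation panel at its published minor allele
# frequencies under HWE, additive per-SNP effects at the published odds
# ratios plus a planted two-locus interaction (checkerboard, +0.8
# log-odds, rs7834206 x rs72616195), case prevalence calibrated to
# 0.9%, lifestyle exposures and 29 food-group intakes with four latent
# dietary patterns.

library(gmdrprs)

seed <- 1L
out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

st <- simulate_study(n_subjects = 56934, seed = seed)

message(sprintf("cohort: %d subjects, %d cases (%.2f%%)",
                nrow(st$cohort), sum(st$cohort$case),
                100 * mean(st$cohort$case)))

# genotypes in both dialects plus the SNP metadata
write_genotypes(st$genotypes, file.path(out_dir, "genotypes.tsv"))
write_genotypes(st$genotypes, file.path(out_dir, "genotypes"),
                dialect = "ped_map")
specs <- snp_info(st$genotypes)
write.table(specs, file.path(out_dir, "snp_specs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

write_cohort(st$cohort, st$manifest, file.path(out_dir, "cohort.tsv"))

message("wrote ", out_dir,
        ": genotypes.tsv, genotypes.ped/.map, snp_specs.tsv, cohort.tsv(+.yaml)")
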
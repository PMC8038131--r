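#!/usr/bin/env Rscript
# Stage 5: risk-allele PRS over the best model and category odds ratios.
#
# Each best-model SNP contributes its risk-allele count (0/1/2), with
# the risk allele oriented by the direction of its adjusted association
# OR. Scores are banded by the preset tertiles when the model size has
# one (5 SNPs: 0-3/4-5/>=6; 6 SNPs: 0-3/4-6/>=7), otherwise by
# empirical tertiles, and medium/high categories are compared with low
# in an adjusted logistic model.

library(gmdrprs)

in_dir <- "results/cohort"
specs_df <- read.delim(file.path(in_dir, "snp_specs.tsv"),
                       colClasses = list(chrom = "character"))
specs <- snp_specs(specs_df$snp_id, specs_df$chrom, specs_df$position,
                   specs_df$minor_allele, specs_df$major_allele,
                   specs_df$maf, gene = specs_df$gene)
g <- read_genotypes(file.path(in_dir, "genotypes.tsv"), specs)
cohort <- read_cohort(file.path(in_dir, "cohort.tsv"), genotypes = g)
screen <- read.delim("results/association_screen.tsv")
best <- readLines("results/best_model.txt")

pm <- orient_risk_alleles(screen, best)
write.table(pm, "results/prs_model.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

profiles <- compute_prs(g, pm)
bounds <- tryCatch(prs_bands(length(best)), error = function(e) "tertile")
profiles <- categorize_prs(profiles, bounds)
write.table(profiles, "results/prs_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ors <- prs_category_or(profiles, cohort,
                       covariates = c("age", "gender", "bmi"))
write.table(format(ors, digits = 4), "results/prs_category_or.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("best model: %d SNPs; bands %s",
                length(best), paste(attr(profiles, "bounds"),
                                    collapse = "/")))
message(sprintf("category sizes: %s",
                paste(names(table(profiles$category)),
                      table(profiles$category), sep = "=",
                      collapse = " ")))
for (i in 2:nrow(ors)) {
  message(sprintf("  %s vs low: OR %.2f (95%% CI %.2f-%.2f, p=%.2e)",
                  ors$category[i], ors$or[i], ors$ci_low[i],
                  ors$ci_high[i], ors$p[i]))
}
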
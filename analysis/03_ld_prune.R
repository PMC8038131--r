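#!/usr/bin/env Rscript
# Stage 3: within-chromosome LD check and pruning.
#
# Haplotype frequencies for each same-chromosome candidate pair are
# estimated by EM from the unphased genotypes; pairs with D' >= 0.4
# are resolved by dropping the SNP with the weaker association, with
# every removal logged.

library(gmdrprs)

in_dir <- "results/cohort"
specs_df <- read.delim(file.path(in_dir, "snp_specs.tsv"),
                       colClasses = list(chrom = "character"))
specs <- snp_specs(specs_df$snp_id, specs_df$chrom, specs_df$position,
                   specs_df$minor_allele, specs_df$major_allele,
                   specs_df$maf, gene = specs_df$gene)
g <- read_genotypes(file.path(in_dir, "genotypes.tsv"), specs)
screen <- read.delim("results/association_screen.tsv")
cand_ids <- read.delim("results/candidates.tsv")$snp_id
cand <- screen[screen$snp_id %in% cand_ids, c("snp_id", "p")]

pr <- prune_by_ld(g, cand, threshold = 0.4)
write.table(format(pr$ld, digits = 4), "results/ld_pairs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pr$removed, "results/ld_removals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(snp_id = pr$kept), "results/ld_kept.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("%d same-chromosome pairs tested; max D' = %.3f",
                nrow(pr$ld),
                if (nrow(pr$ld)) max(pr$ld$d_prime) else NA))
message(sprintf("%d SNP(s) removed at D' >= 0.4; %d candidates kept",
                nrow(pr$removed), length(pr$kept)))
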
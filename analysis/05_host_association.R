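#!/usr/bin/env Rscript
# Stage 5: host-factor analyses.
#
# Hypergeometric prevalence screen across age decades and sex,
# winsorised age-conditioned linear association of ASV abundance with
# BMI/waist/stool frequency, the diet-pattern PCA and the age trends.

suppressMessages(library(gutstruct))

counts <- read_count_table("results/cohort/counts.tsv")
tax <- read_taxonomy("results/cohort/taxonomy.tsv")
tax <- assign_display_names(counts, tax)
meta <- read_metadata("results/cohort/metadata.tsv")
meta <- meta[match(rownames(counts), meta$sample_id), ]

dir.create("results/host", showWarnings = FALSE, recursive = TRUE)

eligible <- prevalence_filter(counts, 0.10)
pres <- counts[, eligible, drop = FALSE] > 0

age_groups <- cut(meta$age, breaks = seq(10, 100, 10), right = FALSE)
scr_age <- prevalence_enrichment(pres, age_groups, alpha = 0.1)
scr_sex <- prevalence_enrichment(pres, meta$sex, alpha = 0.1)
write.table(rbind(scr_age, scr_sex), "results/host/prevalence_screen.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("prevalence screen: %d significant calls over %d tests",
                sum(scr_age$significant) + sum(scr_sex$significant),
                nrow(scr_age) + nrow(scr_sex)))

assoc <- associate_all(counts, meta,
                       factors = c("bmi", "waist", "stool_frequency"),
                       age_var = "age", fdr = 0.2)
write.table(assoc, "results/host/associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- assoc[assoc$significant, ]
message(sprintf("associations at FDR 0.2: %d (of %d tests)",
                nrow(sig), nrow(assoc)))
for (i in seq_len(min(6, nrow(sig))))
  message(sprintf("  %s ~ %s: beta %.2f, q %.3g%s",
                  tax$display_name[match(sig$asv_id[i], tax$asv_id)],
                  sig$factor[i], sig$beta[i], sig$q[i],
                  if (sig$age_adjusted[i]) " (age-adjusted)" else ""))

dp <- diet_pca(meta[, food_group_loadings()$group])
write.table(data.frame(food_group = rownames(dp$loadings),
                       dp$loadings[, 1:2]),
            "results/host/diet_loadings.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
west <- c("noodles", "snacks", "meat")
pc2 <- dp$scores[, 2] * sign(sum(dp$loadings[west, 2]))
message(sprintf("diet PC2 (Westernised) ~ age: rho = %.2f",
                cor(pc2, meta$age, method = "spearman")))

rich <- observed_richness(counts)
adc <- age_diversity_correlation(rich, meta$age, meta$sex)
write.table(adc, "results/host/age_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
aac <- age_abundance_correlation(counts, meta$age, fdr = 0.2)
write.table(aac, "results/host/age_abundance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("age ~ abundance: %d ASVs at FDR 0.2",
                sum(aac$significant)))
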
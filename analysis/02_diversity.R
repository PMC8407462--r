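#!/usr/bin/env Rscript
# Stage 2: community metrics and ordination.
#
# Reads the cohort written by 01_simulate.R, computes per-sample
# richness, the weighted UniFrac distance matrix and its
# principal-coordinate embedding, and the age trend of alpha diversity.

suppressMessages(library(gutstruct))

counts <- read_count_table("results/cohort/counts.tsv")
tax <- read_taxonomy("results/cohort/taxonomy.tsv")
tree <- ape::read.tree("results/cohort/tree.nwk")
meta <- read_metadata("results/cohort/metadata.tsv")
meta <- meta[match(rownames(counts), meta$sample_id), ]

dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)

relg <- relative_abundance(counts, tax, "genus")
top <- sort(colMeans(relg), decreasing = TRUE)[1:10]
message("top genera (mean relative abundance):")
for (g in names(top)) message(sprintf("  %-22s %.3f", g, top[g]))

d <- unifrac_matrix(tree, counts)
write_distance_matrix(d, "results/diversity/unifrac.tsv")
ord <- pcoa_ordination(d, n_axes = 10)
write.table(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates),
            "results/diversity/pcoa.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("PCoA: axis 1/2 explain %.1f%% / %.1f%%",
                100 * ord$proportion_explained[1],
                100 * ord$proportion_explained[2]))

rich <- observed_richness(counts)
ma <- moving_average(meta$age, rich, window = 10)
write.table(ma, "results/diversity/richness_by_age.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("richness: median %.0f ASVs/sample", median(rich)))
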
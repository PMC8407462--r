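#!/usr/bin/env Rscript
# Stage 4: cooccurrence network and microbial clusters.
#
# Builds the dual-criterion association network (Fisher cooccurrence
# FDR < 1e-6 AND positive Spearman FDR < 1e-3, prevalence >= 10%),
# extracts clique-based clusters, and screens for negative quantitative
# associations.

suppressMessages(library(gutstruct))

counts <- read_count_table("results/cohort/counts.tsv")
tax <- read_taxonomy("results/cohort/taxonomy.tsv")
tax <- assign_display_names(counts, tax)

dir.create("results/network", showWarnings = FALSE, recursive = TRUE)

net <- build_network(counts, tax)
message(sprintf("pairs passing cooccurrence: %d, quantitative: %d, both: %d",
                net$criterion_counts[["cooccurrence"]],
                net$criterion_counts[["quantitative"]],
                net$criterion_counts[["edges"]]))

clusters <- find_clusters(net)
for (cid in unique(clusters$cluster)) {
  sub <- clusters[clusters$cluster == cid, ]
  message(sprintf("  %s %-28s %-15s %d ASVs", cid, sub$name[1],
                  sub$phylum[1], nrow(sub)))
}
export_network(net, clusters, "results/network/network.graphml", "graphml")
export_network(net, clusters, "results/network/edges.tsv", "edgelist")
write.table(clusters, "results/network/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

neg <- negative_associations(counts)
write.table(neg, "results/network/negative_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("negative associations: %d pairs (min rho %.2f)",
                nrow(neg), if (nrow(neg)) min(neg$rho) else NA))
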
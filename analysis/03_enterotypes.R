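#!/usr/bin/env Rscript
# Stage 3: enterotype detection and cross-cohort comparison.
#
# Fits the two-component Gaussian mixture on the UniFrac PCoA
# embedding, labels clusters by dominant genus, and reruns the
# published enterotype-ratio worked examples (Korean counts vs foreign
# cohorts reconstructed from printed percentages).

suppressMessages(library(gutstruct))
seed <- 1

counts <- read_count_table("results/cohort/counts.tsv")
tax <- read_taxonomy("results/cohort/taxonomy.tsv")
tax <- assign_display_names(counts, tax)
d <- read_distance_matrix("results/diversity/unifrac.tsv")

dir.create("results/enterotypes", showWarnings = FALSE, recursive = TRUE)

model <- fit_enterotypes(d, counts, tax, K = 2, n_axes = 10, seed = seed)
tab <- table(model$et_names)
message("enterotypes: ", paste(names(tab), tab, collapse = ", "))
write.table(data.frame(sample_id = names(model$et_names),
                       enterotype = model$et_names),
            "results/enterotypes/enterotypes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

korea <- c(536, 354)
cohorts <- list("Beijing/Hangzhou" = c(327, 85), Shanghai = c(22, 3),
                Spain = c(36, 4), Chile = c(30, 11))
rows <- lapply(names(cohorts), function(nm) {
  res <- compare_et_proportions(korea, cohorts[[nm]])
  message(sprintf("%-17s Bacteroides %5.1f%%  chi2 = %6.2f  p = %.3g",
                  nm, 100 * cohorts[[nm]][1] / sum(cohorts[[nm]]),
                  res$statistic, res$p.value))
  data.frame(cohort = nm, n = sum(cohorts[[nm]]),
             chi2 = res$statistic, p = res$p.value)
})
write.table(do.call(rbind, rows), "results/enterotypes/comparisons.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
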
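#' Enterotype recovery on a synthetic reference + external cohort pair
#'
#' Generates a reference cohort, fits enterotypes, then generates an
#' external cohort from the same community model and transfers labels by
#' nearest UniFrac neighbour. Reports the adjusted Rand index of the
#' fitted labels against the planted ones and the transfer accuracy
#' against the external cohort's planted labels.
#'
#' @param n_ref,n_query Reference and external cohort sizes.
#' @param seed Seed controlling both cohorts and the fit.
#' @return List: `ari`, `nn_accuracy`, `et_split` (fraction of the
#'   reference in the Bacteroides enterotype), `genus_labels`.
#' @export
evaluate_enterotype_recovery <- function(n_ref = 800, n_query = 200, seed = 1) {
  ref <- generate_cohort(cohort_spec(n_samples = n_ref, seed = seed))
  d <- unifrac_matrix(ref$tree, ref$counts)
  model <- fit_enterotypes(d, ref$counts, ref$taxonomy, K = 2,
                           seed = seed + 1L)
  ari <- adjustedRandIndex(model$labels, ref$ground_truth$et_labels)
  qry <- generate_cohort(cohort_spec(n_samples = n_query,
                                     seed = seed + 7919L))
  # same spec family: identical ASV panel and tree topology parameters
  both <- rbind(ref$counts, qry$counts)
  d_all <- unifrac_matrix(ref$tree, both)
  d_cross <- d_all[n_ref + seq_len(n_query), seq_len(n_ref), drop = FALSE]
  nn <- assign_enterotype_nn(model$et_names, d_cross)
  list(ari = ari,
       nn_accuracy = mean(nn == qry$ground_truth$et_labels),
       et_split = mean(ref$ground_truth$et_labels == "Bacteroides"),
       fitted_split = mean(model$et_names == "Bacteroides"),
       genus_labels = model$genus_labels)
}

#' Planted-block recovery through the cooccurrence network
#'
#' Generates a cohort, builds the dual-criterion network at the standard
#' thresholds and extracts clusters, then matches each planted block to
#' its best-overlapping recovered cluster.
#'
#' @param n_samples Cohort size.
#' @param seed Seed.
#' @param fdr_cooc,fdr_quant,min_prev Network thresholds.
#' @return List: `jaccard` (per planted block), `mean_jaccard`,
#'   `n_clusters`, `n_edges`.
#' @export
evaluate_block_recovery <- function(n_samples = 800, seed = 1,
                                    fdr_cooc = 1e-6, fdr_quant = 1e-3,
                                    min_prev = 0.10) {
  co <- generate_cohort(cohort_spec(n_samples = n_samples, seed = seed))
  net <- build_network(co$counts, co$taxonomy, fdr_cooc = fdr_cooc,
                       fdr_quant = fdr_quant, min_prev = min_prev)
  cl <- find_clusters(net)
  gt <- co$ground_truth$cluster_membership
  blocks <- sort(unique(gt[!is.na(gt)]))
  jac <- vapply(blocks, function(b) {
    truth <- names(gt)[!is.na(gt) & gt == b]
    best <- 0
    for (cid in unique(cl$cluster)) {
      mem <- cl$member[cl$cluster == cid]
      best <- max(best, length(intersect(truth, mem)) /
                    length(union(truth, mem)))
    }
    best
  }, numeric(1))
  list(jaccard = jac, mean_jaccard = mean(jac),
       n_clusters = length(unique(cl$cluster)),
       n_edges = nrow(net$edges))
}

# Replicate spec for the association calibration: a single-enterotype
# cohort so the only non-null associations are the planted effect and
# its block-mates (in a two-enterotype mixture every taxon tied to the
# enterotype axis is weakly but genuinely associated with any factor
# that carries a planted effect, which would contaminate the null set).
assoc_replicate_spec <- function(seed, effect_table) {
  cohort_spec(n_samples = 120, n_asvs = 60, n_clusters = 3,
              cluster_size = 3, et_proportions = c(1, 0),
              effect_table = effect_table, seed = seed)
}

#' Power and empirical FDR of the host-factor association pipeline
#'
#' Runs replicate synthetic cohorts, each with one planted BMI effect
#' (`beta = 0.5`, factor noise sd 1), through [associate_all()] at
#' FDR 0.2 over a four-factor family (BMI, stool frequency and two null
#' food groups). Power is the detection rate of the planted pair.
#' A call counts as a true discovery when it pairs BMI with the planted
#' ASV or one of its block-mates (which share the planted ASV's latent
#' factor and are therefore genuinely marginally associated); the
#' empirical FDR is the mean over replicates of the false fraction of
#' calls (zero when nothing is called).
#'
#' @param n_reps Number of replicate cohorts.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param fdr FDR level of the association screen.
#' @return List: `power`, `fdr` and the per-replicate vectors.
#' @export
calibrate_association <- function(n_reps = 200, seed = 1, fdr = 0.2) {
  one_eff <- data.frame(asv = "block1_1", factor = "bmi", beta = 0.5,
                        direction = "+", stratum = NA_character_,
                        stringsAsFactors = FALSE)
  detected <- logical(n_reps)
  vr <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    co <- generate_cohort(assoc_replicate_spec(seed + r, one_eff))
    assoc <- associate_all(co$counts, co$metadata,
                           factors = c("bmi", "stool_frequency",
                                       "grain", "fruit"), fdr = fdr)
    gt <- co$ground_truth$cluster_membership
    eff <- co$ground_truth$planted_effects
    truth_asvs <- names(gt)[!is.na(gt) & gt %in% unique(gt[eff$asv_id])]
    calls <- assoc[assoc$significant, , drop = FALSE]
    true_call <- calls$factor == "bmi" & calls$asv_id %in% truth_asvs
    detected[r] <- all(paste(eff$asv_id, "bmi") %in%
                         paste(calls$asv_id, calls$factor))
    vr[r] <- if (nrow(calls) == 0) 0 else mean(!true_call)
  }
  list(power = mean(detected), fdr = mean(vr),
       detected = detected, false_fraction = vr)
}

#' Type-I error of the association pipeline on effect-free cohorts
#'
#' Replicate cohorts with an empty effect table; the rejection rate of
#' the raw per-test p-values at the nominal level estimates the size of
#' the test.
#'
#' @param n_reps Number of replicate cohorts.
#' @param seed Base seed.
#' @param level Nominal level.
#' @return List: `rate` (fraction of p below `level`), `n_tests`.
#' @export
calibrate_association_null <- function(n_reps = 200, seed = 1, level = 0.05) {
  no_eff <- data.frame(asv = character(), factor = character(),
                       beta = numeric(), direction = character(),
                       stratum = character(), stringsAsFactors = FALSE)
  hits <- tot <- 0
  for (r in seq_len(n_reps)) {
    co <- generate_cohort(assoc_replicate_spec(seed + r, no_eff))
    assoc <- associate_all(co$counts, co$metadata,
                           factors = c("bmi", "stool_frequency",
                                       "grain", "fruit"), fdr = 0.2)
    hits <- hits + sum(assoc$p < level)
    tot <- tot + nrow(assoc)
  }
  list(rate = hits / tot, n_tests = tot)
}

#' Type-I error of the PERMANOVA permutation test
#'
#' Draws random group labels, independent of community structure, on a
#' fixed effect-free synthetic cohort and records the rejection rate of
#' the permutation p-value at the nominal level.
#'
#' @param n_reps Number of label draws.
#' @param n_samples Cohort size.
#' @param n_perm Permutations per test.
#' @param seed Seed.
#' @param level Nominal level.
#' @return List: `rate`, `n_reps`.
#' @export
calibrate_permanova_null <- function(n_reps = 1000, n_samples = 40,
                                     n_perm = 99, seed = 1, level = 0.05) {
  co <- generate_cohort(cohort_spec(n_samples = n_samples, n_asvs = 60,
                                    n_clusters = 3, cluster_size = 3,
                                    seed = seed))
  d <- unifrac_matrix(co$tree, co$counts)
  rej <- with_seed(seed + 1L, {
    vapply(seq_len(n_reps), function(r) {
      labels <- sample(rep(c("a", "b"), length.out = n_samples))
      # inner permutations use their own derived seed
      permanova(d, labels, n_perm = n_perm,
                seed = seed + 1000L + r)$p.value <= level
    }, logical(1))
  })
  list(rate = mean(rej), n_reps = n_reps)
}
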
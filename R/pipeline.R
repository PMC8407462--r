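#' Configure an end-to-end pipeline run
#'
#' Thresholds default to the standard analysis settings: samples with
#' more than 10,000 reads; ASVs in at least 10% of samples; FDR 1e-6
#' (cooccurrence), 1e-3 (quantitative), 0.1 (prevalence screen), 0.2
#' (host-factor association); two enterotypes fit on 10 PCoA axes.
#'
#' @param input_dir Directory with `counts.tsv`, `taxonomy.tsv`,
#'   `tree.nwk`, `metadata.tsv` (as written by [write_cohort()]);
#'   `NULL` simulates a cohort instead.
#' @param simulate A [cohort_spec()] used when `input_dir` is `NULL`.
#' @param min_reads,min_prev,fdr_cooc,fdr_quant,fdr_prev,fdr_assoc,K,n_axes,n_perm
#'   Stage parameters (see the stage functions).
#' @param factors Host factors to test; defaults to BMI, waist and
#'   stool frequency.
#' @param seed Master seed; each randomised stage uses `seed + stage
#'   offset`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = cohort_spec(),
                            min_reads = 10000, min_prev = 0.10,
                            fdr_cooc = 1e-6, fdr_quant = 1e-3,
                            fdr_prev = 0.1, fdr_assoc = 0.2,
                            K = 2, n_axes = 10, n_perm = 999,
                            factors = c("bmi", "waist", "stool_frequency"),
                            seed = 1) {
  for (th in c(fdr_cooc, fdr_quant, fdr_prev, fdr_assoc))
    if (!(th > 0 && th < 1)) stop("FDR thresholds must lie strictly in (0, 1)")
  stopifnot(min_prev > 0, min_prev <= 1, K >= 1, n_axes >= 1, n_perm >= 1)
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  structure(list(input_dir = input_dir, simulate = simulate,
                 min_reads = min_reads, min_prev = min_prev,
                 fdr_cooc = fdr_cooc, fdr_quant = fdr_quant,
                 fdr_prev = fdr_prev, fdr_assoc = fdr_assoc, K = K,
                 n_axes = n_axes, n_perm = n_perm, factors = factors,
                 seed = seed), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) -> filter -> diversity -> enterotypes ->
#' cooccurrence network and clusters -> demographic prevalence screen
#' and host-factor associations. Every stage writes its table under
#' `out_dir` and a `summary.json` collects the headline numbers.
#' Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with every stage result and `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message("[gutstruct] ", ...)

  if (is.null(config$input_dir)) {
    log_line("simulating cohort (seed ", config$simulate$seed, ")")
    cohort <- generate_cohort(config$simulate)
    counts <- cohort$counts; tax <- cohort$taxonomy
    tree <- cohort$tree; meta <- cohort$metadata
  } else {
    log_line("reading inputs from ", config$input_dir)
    counts <- read_count_table(file.path(config$input_dir, "counts.tsv"),
                               min_reads = config$min_reads)
    tax <- read_taxonomy(file.path(config$input_dir, "taxonomy.tsv"))
    tax <- assign_display_names(counts, tax)
    tree <- ape::read.tree(file.path(config$input_dir, "tree.nwk"))
    meta <- read_metadata(file.path(config$input_dir, "metadata.tsv"))
    cohort <- NULL
  }
  keep <- rowSums(counts) > config$min_reads
  if (any(!keep)) log_line(sum(!keep), " sample(s) below read threshold dropped")
  counts <- counts[keep, , drop = FALSE]
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  log_line(nrow(counts), " samples x ", ncol(counts), " ASVs")

  d <- unifrac_matrix(tree, counts)
  write_distance_matrix(d, file.path(out_dir, "unifrac.tsv"))
  model <- fit_enterotypes(d, counts, tax, K = config$K,
                           n_axes = config$n_axes, seed = config$seed + 1L)
  et_tab <- table(model$et_names)
  log_line("enterotypes: ", paste(names(et_tab), et_tab, collapse = ", "))
  utils::write.table(
    data.frame(sample_id = names(model$et_names), enterotype = model$et_names),
    file.path(out_dir, "enterotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  net <- build_network(counts, tax, fdr_cooc = config$fdr_cooc,
                       fdr_quant = config$fdr_quant,
                       min_prev = config$min_prev)
  clusters <- find_clusters(net)
  log_line(net$criterion_counts[["edges"]], " network edges, ",
           length(unique(clusters$cluster)), " clusters")
  export_network(net, clusters, file.path(out_dir, "network.graphml"),
                 format = "graphml")
  export_network(net, clusters, file.path(out_dir, "edges.tsv"),
                 format = "edgelist")
  utils::write.table(clusters, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  eligible <- prevalence_filter(counts, config$min_prev)
  age_groups <- cut(meta$age, breaks = seq(10, 100, by = 10), right = FALSE)
  prev_screen <- prevalence_enrichment(counts[, eligible, drop = FALSE] > 0,
                                       age_groups, alpha = config$fdr_prev)
  utils::write.table(prev_screen, file.path(out_dir, "prevalence_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  assoc <- associate_all(counts, meta, factors = config$factors,
                         age_var = "age", fdr = config$fdr_assoc,
                         min_prevalence = config$min_prev)
  utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  food_cols <- food_group_loadings()$group
  dp <- if (all(food_cols %in% colnames(meta)))
    diet_pca(meta[, food_cols]) else NULL
  if (!is.null(dp))
    utils::write.table(
      data.frame(food_group = rownames(dp$loadings), dp$loadings[, 1:2]),
      file.path(out_dir, "diet_loadings.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)

  summary <- list(
    n_samples = nrow(counts), n_asvs = ncol(counts),
    enterotype_counts = as.list(et_tab),
    network_edges = unname(net$criterion_counts[["edges"]]),
    pairs_cooccurrence = unname(net$criterion_counts[["cooccurrence"]]),
    pairs_quantitative = unname(net$criterion_counts[["quantitative"]]),
    n_clusters = length(unique(clusters$cluster)),
    significant_prevalence_calls = sum(prev_screen$significant),
    significant_associations = sum(assoc$significant),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(counts = counts, taxonomy = tax, tree = tree,
                 metadata = meta, distance = d, enterotypes = model,
                 network = net, clusters = clusters,
                 prevalence_screen = prev_screen, associations = assoc,
                 diet = dp, summary = summary, cohort = cohort))
}
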
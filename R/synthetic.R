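# Evaluate expr with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Reference genus panel for the synthetic community
#'
#' Twenty common gut genera with their phylum and the mean genus-level
#' relative-abundance profile of each of the two enterotypes. The
#' dominant-genus anchors (Bacteroides 35.3% / Prevotella 2% /
#' Faecalibacterium 14.2% in the Bacteroides enterotype; Prevotella
#' 37.1% / Bacteroides 10.4% / Faecalibacterium 11.7% in the Prevotella
#' enterotype) are fixed; the remaining mass is spread over minor genera
#' with fixed relative weights so each profile sums to one.
#'
#' @return Data frame with columns `genus`, `phylum`, `prof_bacteroides`,
#'   `prof_prevotella`.
#' @export
default_genus_profiles <- function() {
  g <- data.frame(
    genus = c("Bacteroides", "Prevotella", "Faecalibacterium",
              "Oscillospira", "Ruminococcus", "Roseburia", "Coprococcus",
              "Lachnospira", "Blautia", "Dorea", "Streptococcus",
              "Phascolarctobacterium", "Megamonas", "Parabacteroides",
              "Alistipes", "Sutterella", "Klebsiella", "Escherichia",
              "Bifidobacterium", "Collinsella"),
    phylum = c("Bacteroidetes", "Bacteroidetes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Bacteroidetes",
               "Bacteroidetes", "Proteobacteria", "Proteobacteria",
               "Proteobacteria", "Actinobacteria", "Actinobacteria"),
    stringsAsFactors = FALSE)
  minor_w <- c(Oscillospira = 2.6, Ruminococcus = 2.4, Roseburia = 2.0,
               Coprococcus = 1.8, Lachnospira = 1.5, Blautia = 0.8,
               Dorea = 1.0, Streptococcus = 1.0,
               Phascolarctobacterium = 1.0, Megamonas = 0.8,
               Parabacteroides = 2.0, Alistipes = 1.8, Sutterella = 1.5,
               Klebsiella = 1.2, Escherichia = 1.0,
               Bifidobacterium = 1.2, Collinsella = 0.8)
  anchors_b <- c(Bacteroides = 0.353, Prevotella = 0.020, Faecalibacterium = 0.142)
  anchors_p <- c(Bacteroides = 0.104, Prevotella = 0.371, Faecalibacterium = 0.117)
  fill <- function(anchors) {
    prof <- anchors[g$genus]
    names(prof) <- g$genus
    rest <- minor_w[g$genus[!g$genus %in% names(anchors)]]
    prof[names(rest)] <- rest / sum(rest) * (1 - sum(anchors))
    unname(prof)
  }
  g$prof_bacteroides <- fill(anchors_b)
  g$prof_prevotella <- fill(anchors_p)
  g
}

# Per-genus higher ranks and a small species pool used to label ASVs.
genus_lineage <- function(genus, phylum) {
  class_of <- c(Bacteroidetes = "Bacteroidia", Firmicutes = "Clostridia",
                Proteobacteria = "Gammaproteobacteria",
                Actinobacteria = "Actinobacteria")
  order_of <- c(Bacteroidetes = "Bacteroidales", Firmicutes = "Clostridiales",
                Proteobacteria = "Enterobacteriales",
                Actinobacteria = "Bifidobacteriales")
  family_of <- c(Bacteroides = "Bacteroidaceae", Prevotella = "Prevotellaceae",
                 Parabacteroides = "Porphyromonadaceae",
                 Alistipes = "Rikenellaceae",
                 Faecalibacterium = "Ruminococcaceae",
                 Oscillospira = "Ruminococcaceae",
                 Ruminococcus = "Ruminococcaceae",
                 Roseburia = "Lachnospiraceae", Coprococcus = "Lachnospiraceae",
                 Lachnospira = "Lachnospiraceae", Blautia = "Lachnospiraceae",
                 Dorea = "Lachnospiraceae", Streptococcus = "Streptococcaceae",
                 Phascolarctobacterium = "Veillonellaceae",
                 Megamonas = "Veillonellaceae",
                 Sutterella = "Alcaligenaceae",
                 Klebsiella = "Enterobacteriaceae",
                 Escherichia = "Enterobacteriaceae",
                 Bifidobacterium = "Bifidobacteriaceae",
                 Collinsella = "Coriobacteriaceae")
  list(class = unname(class_of[phylum]), order = unname(order_of[phylum]),
       family = unname(family_of[genus]))
}

species_pool <- function(genus) {
  pool <- list(
    Bacteroides = c("Bacteroides uniformis", "Bacteroides ovatus", "Bacteroides caccae"),
    Prevotella = c("Prevotella copri", "Prevotella copri", "Prevotella stercorea"),
    Faecalibacterium = c("Faecalibacterium prausnitzii", "Faecalibacterium prausnitzii"),
    Blautia = c("Blautia obeum"), Dorea = c("Dorea longicatena"),
    Bifidobacterium = c("Bifidobacterium longum"),
    Collinsella = c("Collinsella aerofaciens"),
    Alistipes = c("Alistipes putredinis"))
  if (genus %in% names(pool)) pool[[genus]] else character(0)
}

#' Specify a synthetic cohort
#'
#' Collects and validates every parameter of the synthetic cohort
#' generator. Defaults reproduce the statistical structure of a large
#' urban healthy cohort: a 60/40 two-enterotype mixture, the dominant
#' genus composition of each enterotype, age 55.6 +/- 15.0 years, 77.5%
#' female, log-normal library sizes around 30,000 reads, planted
#' cooccurrence blocks, and planted ASV-BMI effects of 0.5 factor units
#' per standard deviation of log abundance.
#'
#' @param n_samples Number of samples.
#' @param n_asvs Number of ASVs.
#' @param et_proportions Mixing proportions of the (Bacteroides,
#'   Prevotella) enterotypes; must sum to 1.
#' @param genus_profiles Data frame as from [default_genus_profiles()].
#' @param n_clusters Number of planted cooccurrence blocks; each block is
#'   a minor genus whose members share a latent factor.
#' @param cluster_size ASVs per planted block (at least 3 so each block
#'   can form a 3-clique).
#' @param effect_table Data frame with columns `asv` (index into the
#'   planted-block ASVs or an explicit ASV id), `factor`, `beta`,
#'   `direction`, and optionally `stratum` (`"female"`/`"male"`/NA).
#'   `NULL` plants `beta = 0.5` BMI effects on the first ASV of up to
#'   three blocks.
#' @param age_mean,age_sd Age distribution (years).
#' @param frac_female Proportion of female participants.
#' @param lib_mean,lib_sdlog Log-normal library-size distribution (mean
#'   reads; sd on the log scale). Draws are floored just above 10,000
#'   reads so the default cohort survives the standard read filter.
#' @param dirichlet_conc Concentration of the per-sample genus Dirichlet
#'   perturbation (larger = less compositional noise).
#' @param asv_noise_sd,block_sd Log-normal noise sd per ASV and the sd of
#'   the shared block factor; equal values give an expected within-block
#'   log-abundance correlation of 0.5.
#' @param block_prevalence Marginal presence probability of block ASVs
#'   (structural zeros driven by the shared factor).
#' @param factor_noise_sd Residual sd of host factors that carry planted
#'   effects.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 890, n_asvs = 300,
                        et_proportions = c(0.60, 0.40),
                        genus_profiles = default_genus_profiles(),
                        n_clusters = 5, cluster_size = 5,
                        effect_table = NULL,
                        age_mean = 55.6, age_sd = 15.0, frac_female = 0.775,
                        lib_mean = 30000, lib_sdlog = 0.35,
                        dirichlet_conc = 100,
                        asv_noise_sd = 0.8, block_sd = 0.8,
                        block_prevalence = 0.55,
                        factor_noise_sd = 1.0,
                        seed = 1) {
  stopifnot(n_samples >= 1, n_asvs >= 2, age_sd > 0, lib_mean > 0)
  if (abs(sum(et_proportions) - 1) > 1e-8 || any(et_proportions < 0))
    stop("et_proportions must be a probability vector summing to 1")
  if (frac_female < 0 || frac_female > 1) stop("frac_female must be in [0, 1]")
  if (n_clusters > 0 && cluster_size < 3)
    stop("cluster_size must be at least 3 so a block can form a clique")
  if (n_clusters * cluster_size > n_asvs)
    stop("invalid spec: cluster_size * n_clusters exceeds n_asvs")
  block_candidates <- c("Parabacteroides", "Ruminococcus", "Streptococcus",
                        "Sutterella", "Collinsella", "Roseburia",
                        "Alistipes", "Klebsiella")
  if (n_clusters > length(block_candidates))
    stop("at most ", length(block_candidates), " planted blocks supported")
  if (is.null(effect_table)) {
    k <- min(3, n_clusters)
    effect_table <- if (k > 0)
      data.frame(asv = paste0("block", seq_len(k), "_1"),
                 factor = "bmi", beta = 0.5, direction = "+",
                 stratum = NA_character_, stringsAsFactors = FALSE)
    else
      data.frame(asv = character(), factor = character(), beta = numeric(),
                 direction = character(), stratum = character(),
                 stringsAsFactors = FALSE)
  }
  if (!"stratum" %in% colnames(effect_table))
    effect_table$stratum <- rep(NA_character_, nrow(effect_table))
  structure(list(
    n_samples = n_samples, n_asvs = n_asvs, et_proportions = et_proportions,
    genus_profiles = genus_profiles, n_clusters = n_clusters,
    cluster_size = cluster_size, effect_table = effect_table,
    age_mean = age_mean, age_sd = age_sd, frac_female = frac_female,
    lib_mean = lib_mean, lib_sdlog = lib_sdlog,
    dirichlet_conc = dirichlet_conc, asv_noise_sd = asv_noise_sd,
    block_sd = block_sd, block_prevalence = block_prevalence,
    factor_noise_sd = factor_noise_sd,
    block_genera = block_candidates[seq_len(n_clusters)],
    seed = seed), class = "cohort_spec")
}

# Allocate ASVs to genera: block genera get exactly cluster_size ASVs,
# the rest are split proportionally to the mean genus profile (min 2).
allocate_asvs <- function(spec) {
  g <- spec$genus_profiles
  mean_prof <- spec$et_proportions[1] * g$prof_bacteroides +
    spec$et_proportions[2] * g$prof_prevotella
  n_block <- spec$n_clusters * spec$cluster_size
  is_block <- g$genus %in% spec$block_genera
  n_free <- spec$n_asvs - n_block
  free_idx <- which(!is_block)
  if (n_free < 2 * length(free_idx))
    stop("n_asvs too small: need at least ", n_block + 2 * length(free_idx))
  w <- mean_prof[free_idx] / sum(mean_prof[free_idx])
  alloc <- pmax(2L, floor(w * n_free))
  # distribute the remainder to the largest genera
  while (sum(alloc) < n_free) {
    i <- which.max(w * n_free - alloc)
    alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > n_free) {
    i <- which.max(alloc)
    alloc[i] <- alloc[i] - 1L
  }
  out <- integer(nrow(g))
  out[free_idx] <- alloc
  out[is_block] <- spec$cluster_size
  names(out) <- g$genus
  out
}

#' Generate a random genus-coalescent phylogenetic tree
#'
#' Builds a rooted binary tree over ASVs in which ASVs of the same genus
#' always coalesce before joining other genera, so that UniFrac
#' distances reflect the taxonomy. Within-genus branches are short,
#' backbone branches long.
#'
#' @param asv_ids Character vector of unique leaf labels.
#' @param genus_of_asv Genus of each ASV (same length).
#' @param seed Integer seed.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
generate_tree <- function(asv_ids, genus_of_asv, seed = 1) {
  if (length(asv_ids) < 2) stop("need at least 2 ASVs")
  if (anyDuplicated(asv_ids)) stop("duplicate ASV ids")
  stopifnot(length(asv_ids) == length(genus_of_asv))
  join_random <- function(parts, bl_min, bl_max) {
    # random sequential pairing into a binary subtree (Newick fragments)
    while (length(parts) > 1) {
      pick <- sample.int(length(parts), 2)
      bl <- stats::runif(2, bl_min, bl_max)
      merged <- sprintf("(%s:%.6f,%s:%.6f)", parts[[pick[1]]], bl[1],
                        parts[[pick[2]]], bl[2])
      parts <- c(parts[-pick], merged)
    }
    parts[[1]]
  }
  with_seed(seed, {
    genera <- unique(genus_of_asv)
    subtrees <- vapply(genera, function(g) {
      tips <- asv_ids[genus_of_asv == g]
      if (length(tips) == 1) tips else join_random(as.list(tips), 0.01, 0.10)
    }, character(1))
    newick <- if (length(subtrees) == 1) {
      # single genus: the genus subtree is the whole tree
      if (length(asv_ids) == 2) {
        subtrees[[1]]
      } else subtrees[[1]]
    } else join_random(as.list(subtrees), 0.10, 0.50)
    ape::read.tree(text = paste0(newick, ";"))
  })
}

#' Generate a synthetic gut-microbiome cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: each sample's enterotype is drawn from `et_proportions`; its
#' genus composition is a Dirichlet perturbation of that enterotype's
#' genus profile; ASVs receive within-genus weights with log-normal
#' per-sample noise; planted blocks share a latent Gaussian factor that
#' drives both structural presence (probit) and log abundance, inducing
#' cooccurrence and positive rank correlation; counts are multinomial
#' draws at log-normal library sizes. Host metadata includes age, sex,
#' BMI, waist, stool frequency and 17 food-group intakes driven by two
#' latent diet axes, the second negatively coupled to age (rank
#' correlation about -0.51). Planted effects add `beta` times the
#' z-scored log relative abundance of an ASV to the named host factor.
#'
#' @param spec A [cohort_spec()].
#' @return List with `counts` (integer matrix samples x ASVs),
#'   `taxonomy` (data frame with display names), `tree` (`phylo`),
#'   `metadata` (data frame), and `ground_truth` (list with `et_labels`,
#'   `cluster_membership`, `planted_effects`, `diet_axes`,
#'   `library_sizes`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$genus_profiles
  alloc <- allocate_asvs(spec)
  n <- spec$n_samples
  with_seed(spec$seed, {
    # --- ASV identity, taxonomy, tree -------------------------------
    genus_of_asv <- rep(g$genus, alloc)
    phylum_of_asv <- rep(g$phylum, alloc)
    n_asv <- length(genus_of_asv)
    asv_ids <- sprintf("ASV_%04d", seq_len(n_asv))
    species <- character(n_asv)
    for (gn in unique(genus_of_asv)) {
      idx <- which(genus_of_asv == gn)
      sp <- species_pool(gn)
      k <- min(length(sp), length(idx))
      if (k > 0) species[idx[seq_len(k)]] <- sp[seq_len(k)]
    }
    lin <- lapply(seq_len(n_asv), function(i)
      genus_lineage(genus_of_asv[i], phylum_of_asv[i]))
    taxonomy <- data.frame(
      asv_id = asv_ids, kingdom = "Bacteria", phylum = phylum_of_asv,
      class = vapply(lin, `[[`, "", "class"),
      order = vapply(lin, `[[`, "", "order"),
      family = vapply(lin, `[[`, "", "family"),
      genus = genus_of_asv, species = species, stringsAsFactors = FALSE)
    tree <- generate_tree(asv_ids, genus_of_asv,
                          seed = spec$seed + 104729L)

    # --- block structure -------------------------------------------
    block_of_asv <- rep(NA_integer_, n_asv)
    for (b in seq_len(spec$n_clusters))
      block_of_asv[genus_of_asv == spec$block_genera[b]] <- b

    # within-genus base weights: geometric rank-abundance for free
    # genera, flat for block genera so members behave symmetrically
    w <- numeric(n_asv)
    for (gn in unique(genus_of_asv)) {
      idx <- which(genus_of_asv == gn)
      w[idx] <- if (!is.na(block_of_asv[idx[1]])) rep(1, length(idx))
      else exp(-0.7 * (seq_along(idx) - 1))
      w[idx] <- w[idx] / sum(w[idx])
    }

    # --- community draws -------------------------------------------
    et <- sample.int(length(spec$et_proportions), n, replace = TRUE,
                     prob = spec$et_proportions)
    prof <- cbind(g$prof_bacteroides, g$prof_prevotella)
    lib <- pmax(10001, round(stats::rlnorm(
      n, meanlog = log(spec$lib_mean) - spec$lib_sdlog^2 / 2,
      sdlog = spec$lib_sdlog)))
    genus_index <- match(genus_of_asv, g$genus)
    thr <- stats::qnorm(1 - spec$block_prevalence)
    counts <- matrix(0L, n, n_asv, dimnames = list(
      sprintf("S%04d", seq_len(n)), asv_ids))
    for (s in seq_len(n)) {
      gprop <- rdirichlet1(spec$dirichlet_conc * prof[, et[s]])
      lambda <- gprop[genus_index] * w *
        exp(stats::rnorm(n_asv, 0, spec$asv_noise_sd))
      if (spec$n_clusters > 0) {
        f <- stats::rnorm(spec$n_clusters)
        bi <- !is.na(block_of_asv)
        fb <- f[block_of_asv[bi]]
        present <- (sqrt(0.5) * fb +
                      sqrt(0.5) * stats::rnorm(sum(bi))) > thr
        lambda[bi] <- lambda[bi] * exp(spec$block_sd * fb) * present
      }
      counts[s, ] <- as.integer(stats::rmultinom(1, lib[s], lambda / sum(lambda)))
    }

    # --- host metadata ---------------------------------------------
    age <- pmin(90, pmax(19, stats::rnorm(n, spec$age_mean, spec$age_sd)))
    sex <- ifelse(stats::runif(n) < spec$frac_female, "female", "male")
    z_age <- (age - mean(age)) / stats::sd(age)
    diet1 <- stats::rnorm(n, 0, 2.2)
    diet2 <- -0.51 * z_age + sqrt(1 - 0.51^2) * stats::rnorm(n)
    foods <- food_group_loadings()
    # baseline far from zero so the nonnegativity floor is never active
    food_mat <- sapply(seq_len(nrow(foods)), function(i)
      pmax(0, 8 + foods$l1[i] * diet1 + foods$l2[i] * diet2 +
             stats::rnorm(n, 0, 0.8)))
    colnames(food_mat) <- foods$group
    bmi <- rep(23.8, n)
    waist <- rep(81, n)
    stool_frequency <- sample(1:7, n, replace = TRUE,
                              prob = c(.05, .10, .15, .30, .20, .12, .08))
    meta <- data.frame(sample_id = rownames(counts), age = age, sex = sex,
                       bmi = bmi, waist = waist,
                       stool_frequency = stool_frequency, food_mat,
                       stringsAsFactors = FALSE, check.names = FALSE)

    # --- planted host-factor effects -------------------------------
    eff <- spec$effect_table
    if (nrow(eff)) {
      rel <- counts / rowSums(counts)
      eff$asv_id <- vapply(eff$asv, function(a) {
        if (grepl("^block[0-9]+_[0-9]+$", a)) {
          b <- as.integer(sub("^block([0-9]+)_.*$", "\\1", a))
          j <- as.integer(sub("^block[0-9]+_([0-9]+)$", "\\1", a))
          asv_ids[which(block_of_asv == b)[j]]
        } else a
      }, character(1))
      for (i in seq_len(nrow(eff))) {
        x <- rel[, eff$asv_id[i]]
        if (all(x == 0)) next
        lx <- log(x + min(x[x > 0]) / 2)
        z <- (lx - mean(lx)) / stats::sd(lx)
        rows <- if (is.na(eff$stratum[i])) rep(TRUE, n) else sex == eff$stratum[i]
        meta[[eff$factor[i]]][rows] <- meta[[eff$factor[i]]][rows] +
          eff$beta[i] * z[rows]
      }
    }
    # residual noise on factors (after effects, so beta is the estimand)
    meta$bmi <- meta$bmi + stats::rnorm(n, 0, spec$factor_noise_sd)
    meta$waist <- meta$waist + 2.2 * (meta$bmi - 23.8) + stats::rnorm(n, 0, 1)

    ground_truth <- list(
      et_labels = stats::setNames(c("Bacteroides", "Prevotella")[et],
                                  rownames(counts)),
      cluster_membership = stats::setNames(block_of_asv, asv_ids),
      planted_effects = eff,
      diet_axes = cbind(diet1 = diet1, diet2 = diet2),
      library_sizes = stats::setNames(lib, rownames(counts)),
      dispersion = list(dirichlet_conc = spec$dirichlet_conc,
                        asv_noise_sd = spec$asv_noise_sd,
                        block_sd = spec$block_sd))
    list(counts = counts,
         taxonomy = assign_display_names(counts, taxonomy),
         tree = tree, metadata = meta, ground_truth = ground_truth,
         spec = spec)
  })
}

#' Food groups and their latent diet-axis loadings
#'
#' The 17 food groups the generator emulates and their loadings on the
#' two latent diet axes: axis 1 is grain-dominated (staple intake);
#' axis 2 contrasts a Westernised diet (noodles, snacks, meat, sweets)
#' against a traditional one (vegetables, seaweed, soybean, kimchi) and
#' is negatively coupled to age.
#'
#' @return Data frame with columns `group`, `l1`, `l2`.
#' @export
food_group_loadings <- function() {
  data.frame(
    group = c("grain", "noodles", "bread", "snacks", "meat", "fish",
              "eggs", "dairy", "vegetables", "kimchi", "seaweed",
              "soybean", "fruit", "mushroom", "beverages", "alcohol",
              "sweets"),
    l1 = c(1.3, 0, -0.6, 0, 0, 0.5, 0.4, -0.5, 0, 0, 0, 0, 0.3, 0,
           0, 0.3, 0),
    l2 = c(0, 0.8, 0, 0.8, 0.7, 0, 0, 0, -0.8, -0.5, -0.7, -0.5, 0,
           -0.4, 0.3, 0, 0.4),
    stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Writes the four standard pipeline inputs (count TSV, taxonomy TSV,
#' Newick tree, metadata TSV) plus a ground-truth JSON.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_taxonomy(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  gt <- cohort$ground_truth
  gt$diet_axes <- as.data.frame(gt$diet_axes)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
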
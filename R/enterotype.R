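#' Fit enterotypes with a Gaussian mixture on PCoA coordinates
#'
#' Embeds the weighted UniFrac distance matrix with principal-coordinate
#' analysis and fits a `K`-component Gaussian mixture on the leading
#' axes. Each cluster is then labelled by the genus with the highest
#' mean relative abundance among its samples.
#'
#' @param d Distance matrix (samples x samples).
#' @param counts Count matrix (same samples) used for genus labelling.
#' @param tax Taxonomy data frame.
#' @param K Number of mixture components (enterotypes).
#' @param n_axes Number of PCoA axes used for the fit.
#' @param seed Seed for the mixture initialisation.
#' @param model mclust covariance model of the mixture. The default
#'   `"EEE"` (covariance pooled across components) keeps the likelihood
#'   well behaved on the moderate-dimensional embedding; unconstrained
#'   per-component covariances (`"VVV"`) admit degenerate spike optima
#'   there. If the chosen model fails to fit, a spherical (`"EII"`)
#'   refit is attempted and logged.
#' @return An `enterotype_model` list: `labels` (per-sample cluster
#'   index), `genus_labels` (per-cluster dominant genus), `et_names`
#'   (per-sample genus label), `ordination`, `K`, `mixture` (the fitted
#'   `Mclust` object), `bic_scan`.
#' @export
fit_enterotypes <- function(d, counts, tax, K = 2, n_axes = 10, seed = 1,
                            model = "EEE") {
  d <- as.matrix(d)
  if (K > nrow(d)) stop("K cannot exceed the number of samples")
  ord <- pcoa_ordination(d, n_axes = min(n_axes, nrow(d) - 1))
  X <- ord$coordinates
  if (K == 1) {
    labels <- stats::setNames(rep(1L, nrow(d)), rownames(d))
    fit <- NULL
  } else {
    em_fit <- function(mn) with_seed(seed, {
      km <- stats::kmeans(X, centers = K, nstart = 10)
      tryCatch(me(modelName = mn, data = X,
                          z = unmap(km$cluster)),
               error = function(e) NULL)
    })
    fit <- em_fit(model)
    if (is.null(fit) || anyNA(fit$z)) {
      # degenerate covariance: refit with a regularised (spherical) model
      message("mixture fit degenerate; refitting with spherical covariance")
      fit <- em_fit("EII")
    }
    fit$classification <- apply(fit$z, 1, which.max)
    labels <- stats::setNames(as.integer(fit$classification), rownames(d))
  }
  genus_rel <- relative_abundance(counts, tax, level = "genus")
  genus_labels <- vapply(seq_len(K), function(k) {
    m <- colMeans(genus_rel[labels == k, , drop = FALSE])
    names(which.max(m))
  }, character(1))
  if (anyDuplicated(genus_labels))
    genus_labels <- make.unique(genus_labels, sep = " ")
  bic <- if (K > 1) with_seed(seed, tryCatch(
    mclustBIC(X, G = 2:6, verbose = FALSE), error = function(e) NULL))
  else NULL
  structure(list(labels = labels, genus_labels = genus_labels,
                 et_names = stats::setNames(genus_labels[labels], names(labels)),
                 ordination = ord, K = K, mixture = fit, bic_scan = bic),
            class = "enterotype_model")
}

#' Transfer enterotype labels to external samples by nearest neighbour
#'
#' Each query sample receives the enterotype of the reference sample at
#' the shortest distance; ties go to the reference sample with the
#' smallest index.
#'
#' @param ref_labels Per-reference-sample enterotype labels (vector, in
#'   reference-column order of `d_cross`).
#' @param d_cross Query x reference distance matrix.
#' @return Vector of labels, one per query row.
#' @export
assign_enterotype_nn <- function(ref_labels, d_cross) {
  d_cross <- as.matrix(d_cross)
  if (ncol(d_cross) != length(ref_labels))
    stop("d_cross must have one column per reference sample")
  if (any(!is.finite(d_cross))) stop("missing distances in d_cross")
  nn <- apply(d_cross, 1, which.min)  # which.min takes the first minimum
  stats::setNames(ref_labels[nn], rownames(d_cross))
}

#' Chi-squared comparison of enterotype proportions between two cohorts
#'
#' 2x2 chi-squared test of independence with Yates continuity
#' correction on the (Bacteroides, Prevotella) counts of a reference and
#' another cohort.
#'
#' @param ref_counts,other_counts Length-2 nonnegative integer vectors.
#' @return List with `statistic`, `p.value`, `table`, and `flag`
#'   (`"zero-margin"` when a margin is empty and the test is undefined).
#' @export
compare_et_proportions <- function(ref_counts, other_counts) {
  stopifnot(length(ref_counts) == 2, length(other_counts) == 2,
            all(ref_counts >= 0), all(other_counts >= 0),
            sum(ref_counts) > 0, sum(other_counts) > 0)
  tab <- rbind(reference = ref_counts, other = other_counts)
  colnames(tab) <- c("ET1", "ET2")
  if (any(colSums(tab) == 0))
    return(list(statistic = NA_real_, p.value = NA_real_, table = tab,
                flag = "zero-margin"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), p.value = ct$p.value, table = tab,
       flag = NULL)
}

# Within-group sum of squared distances divided by group size, summed
# over groups, from the squared-distance matrix D2 and a label vector.
ss_within <- function(D2, labels) {
  s <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Pseudo-F from the distance-matrix sum-of-squares decomposition
#' (`SS_total = sum d^2 / n` over pairs; `SS_within` summed per group),
#' with a label-permutation p-value `(1 + #(F* >= F)) / (1 + n_perm)`.
#' With `exhaustive = TRUE` all `n!` label permutations are enumerated
#' and the p-value is the exact proportion with `F* >= F` (identity
#' included).
#'
#' @param d Distance matrix.
#' @param labels Group labels (at least two nonempty groups).
#' @param n_perm Number of random permutations.
#' @param seed Seed for the permutations.
#' @param exhaustive Enumerate all label permutations (small n only).
#' @return List with `F`, `p.value`, `n_perm`, and the sums of squares.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1, exhaustive = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  groups <- unique(labels)
  g <- length(groups)
  if (g < 2) stop("need at least two groups")
  if (any(table(labels) == 0)) stop("empty group")
  D2 <- d^2
  ss_tot <- sum(D2) / (2 * n)
  if (ss_tot == 0) stop("all distances are zero; pseudo-F undefined")
  f_stat <- function(lab) {
    ssw <- ss_within(D2, lab)
    ((ss_tot - ssw) / (g - 1)) / (ssw / (n - g))
  }
  ssw_obs <- ss_within(D2, labels)
  F_obs <- ((ss_tot - ssw_obs) / (g - 1)) / (ssw_obs / (n - g))
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration is limited to n <= 8")
    perms <- all_permutations(n)
    F_perm <- apply(perms, 1, function(p) f_stat(labels[p]))
    p <- mean(F_perm >= F_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    F_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      f_stat(sample(labels)), numeric(1)))
    p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_perm)
  }
  list(F = F_obs, p.value = p, n_perm = n_perm, ss_total = ss_tot,
       ss_within = ssw_obs, ss_between = ss_tot - ssw_obs)
}

# All permutations of 1..n as a matrix (n! rows).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Average-distance comparison of a foreign cohort with the reference
#'
#' For each foreign sample of the target enterotype: the mean distance
#' to all reference samples of that enterotype. For each reference
#' sample of that enterotype: the mean distance to the other reference
#' samples of the enterotype (self excluded). The two sets of averages
#' are compared with a two-sided Mann-Whitney U test (exact for small
#' tie-free samples, normal approximation with tie correction
#' otherwise).
#'
#' @param d_cross Foreign x reference distance matrix.
#' @param d_ref Reference x reference distance matrix.
#' @param ref_labels Reference enterotype labels (column order of
#'   `d_cross`).
#' @param query_labels Foreign enterotype labels (row order of
#'   `d_cross`).
#' @param target_et The enterotype to compare.
#' @return List with `U`, `p.value`, `foreign_avg`, `reference_avg`.
#' @export
avg_distance_test <- function(d_cross, d_ref, ref_labels, query_labels,
                              target_et) {
  d_cross <- as.matrix(d_cross); d_ref <- as.matrix(d_ref)
  ref_idx <- which(ref_labels == target_et)
  q_idx <- which(query_labels == target_et)
  if (length(ref_idx) < 2) stop("need at least 2 reference samples in target enterotype")
  if (length(q_idx) < 2) stop("need at least 2 foreign samples in target enterotype")
  foreign_avg <- rowMeans(d_cross[q_idx, ref_idx, drop = FALSE])
  sub <- d_ref[ref_idx, ref_idx, drop = FALSE]
  reference_avg <- rowSums(sub) / (length(ref_idx) - 1)  # self distance is 0
  if (stats::sd(c(foreign_avg, reference_avg)) == 0) {
    # fully tied averages carry no evidence either way
    wt <- list(statistic = length(foreign_avg) * length(reference_avg) / 2,
               p.value = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(foreign_avg, reference_avg,
                                              alternative = "two.sided"))
  }
  list(U = unname(wt$statistic), p.value = wt$p.value,
       foreign_avg = unname(foreign_avg), reference_avg = unname(reference_avg))
}
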
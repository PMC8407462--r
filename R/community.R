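#' Aggregate a count matrix to a taxonomic level
#'
#' @param counts Count matrix (samples x ASVs).
#' @param tax Taxonomy data frame; required for any `level` other than
#'   `"ASV"`.
#' @param level `"ASV"`, `"genus"`, `"phylum"`, or any rank column of the
#'   taxonomy table.
#' @return Count matrix (samples x taxa) summed within level; unassigned
#'   taxa are pooled under `"Unassigned"`.
#' @export
aggregate_counts <- function(counts, tax = NULL, level = "ASV") {
  if (identical(level, "ASV")) return(counts)
  if (is.null(tax)) stop("taxonomy required for level '", level, "'")
  if (!level %in% colnames(tax)) stop("unknown taxonomy level '", level, "'")
  tax <- tax[match(colnames(counts), tax$asv_id), , drop = FALSE]
  lab <- as.character(tax[[level]])
  lab[is.na(lab) | !nzchar(lab)] <- "Unassigned"
  groups <- unique(lab)
  out <- vapply(groups, function(g)
    rowSums(counts[, lab == g, drop = FALSE]), numeric(nrow(counts)))
  if (nrow(counts) == 1L) out <- matrix(out, nrow = 1, dimnames = list(rownames(counts), groups))
  out
}

#' Relative abundance per sample
#'
#' The relative abundance of a taxonomic group in a sample is its read
#' count divided by the sample's total reads; aggregation to higher
#' levels sums counts before dividing, so rows always sum to one.
#'
#' @inheritParams aggregate_counts
#' @return Numeric matrix (samples x taxa), rows summing to 1.
#' @export
relative_abundance <- function(counts, tax = NULL, level = "ASV") {
  m <- aggregate_counts(counts, tax, level)
  tot <- rowSums(m)
  if (any(tot == 0)) stop("sample(s) with zero total reads: ",
                          paste(utils::head(rownames(m)[tot == 0], 3), collapse = ", "))
  m / tot
}

#' Prevalence of each taxon
#'
#' Proportion of samples in which a taxonomic group has nonzero reads.
#'
#' @inheritParams aggregate_counts
#' @return Named numeric vector in `[0, 1]`.
#' @export
prevalence <- function(counts, tax = NULL, level = "ASV") {
  m <- aggregate_counts(counts, tax, level)
  colMeans(m > 0)
}

#' Observed ASV richness per sample
#'
#' @param counts Count matrix (samples x ASVs).
#' @return Named integer vector: number of ASVs with nonzero reads.
#' @export
observed_richness <- function(counts) {
  r <- rowSums(counts > 0)
  storage.mode(r) <- "integer"
  r
}

# Branch mass matrix: for each tree edge, the proportion of each sample's
# abundance that descends from that edge. Rows = samples, cols = edges of
# tree$edge; computed by accumulating leaf masses up the tree in one pass
# over a postorder edge ordering.
branch_mass <- function(tree, rel) {
  missing <- setdiff(colnames(rel), tree$tip.label)
  if (length(missing))
    stop("leaf absent from tree: ", paste(utils::head(missing, 3), collapse = ", "))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # node mass per sample, filled bottom-up
  node_mass <- matrix(0, nrow(rel), n_node)
  node_mass[, match(colnames(rel), tree$tip.label)] <- rel
  tree <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    node_mass[, parent] <- node_mass[, parent] + node_mass[, child]
  }
  list(mass = node_mass[, tree$edge[, 2], drop = FALSE],
       lengths = tree$edge.length)
}

#' Weighted UniFrac distance between two communities
#'
#' Unnormalised weighted UniFrac: the sum over branches of branch length
#' times the absolute difference in the proportion of each community's
#' abundance descending from the branch.
#'
#' @param tree Rooted `phylo` tree whose tips cover the taxa.
#' @param a,b Named relative-abundance vectors over tree tips (each
#'   summing to 1).
#' @return Nonnegative distance; 0 for identical communities.
#' @export
weighted_unifrac <- function(tree, a, b) {
  rel <- rbind(a, b)
  if (is.null(colnames(rel))) stop("abundance vectors must be named by tip label")
  bm <- branch_mass(tree, rel)
  sum(bm$lengths * abs(bm$mass[1, ] - bm$mass[2, ]))
}

#' Pairwise weighted UniFrac distance matrix
#'
#' Computes all pairwise unnormalised weighted UniFrac distances from a
#' count matrix (converted to relative abundance internally). The branch
#' masses are assembled once per sample and the pairwise sum reduces to a
#' Manhattan distance between length-weighted branch-mass profiles, so
#' the computation scales to cohort-sized inputs.
#'
#' @param tree Rooted `phylo` tree covering all ASVs in `counts`.
#' @param counts Count matrix (samples x ASVs) with nonzero row sums, or
#'   a relative-abundance matrix (rows summing to 1).
#' @return Symmetric distance matrix with sample dimnames.
#' @export
unifrac_matrix <- function(tree, counts) {
  rel <- counts / rowSums(counts)
  bm <- branch_mass(tree, rel)
  w <- sweep(bm$mass, 2, bm$lengths, `*`)
  d <- as.matrix(stats::dist(w, method = "manhattan"))
  dimnames(d) <- list(rownames(counts), rownames(counts))
  d
}

#' Principal-coordinate analysis (classical multidimensional scaling)
#'
#' Double-centres the squared distance matrix, eigendecomposes it and
#' keeps the leading axes by eigenvalue. Negative eigenvalues (distance
#' matrices that are not exactly Euclidean) are reported but their axes
#' are dropped.
#'
#' @param d Symmetric distance matrix.
#' @param n_axes Number of axes to return (capped at the number of
#'   positive eigenvalues).
#' @return List with `coordinates` (samples x axes), `eigenvalues` (all,
#'   descending), `proportion_explained` (over positive eigenvalues, for
#'   the returned axes) and `n_negative_eigenvalues`.
#' @export
pcoa_ordination <- function(d, n_axes = 10) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  n <- nrow(d)
  if (n_axes > n - 1) stop("n_axes must be at most n_samples - 1")
  # double-centering: B = (I - 11'/n) (-D^2/2) (I - 11'/n)
  A <- -0.5 * d^2
  B <- sweep(A, 1, rowMeans(A))
  B <- sweep(B, 2, colMeans(B))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- eig$values
  pos <- which(vals > max(vals[1], 0) * 1e-12 & vals > 0)
  keep <- utils::head(pos, n_axes)
  if (length(keep) == 0) {
    # fully degenerate input (e.g. all-zero distances): a zero embedding
    coords <- matrix(0, n, n_axes)
  } else {
    coords <- eig$vectors[, keep, drop = FALSE] %*% diag(sqrt(vals[keep]), length(keep))
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = vals,
       proportion_explained = if (length(pos)) vals[keep] / sum(vals[pos]) else numeric(0),
       n_negative_eigenvalues = sum(vals < -max(abs(vals)) * 1e-12))
}

#' Moving average of a response over an age grid
#'
#' For each grid age `a`, the mean of `y` over samples whose age lies in
#' `[a - window/2, a + window/2)`; grid points with empty windows are
#' omitted.
#'
#' @param x Ages (or any ordinate).
#' @param y Values to smooth.
#' @param window Window width in the units of `x`.
#' @param grid Evaluation grid; defaults to unit steps spanning `x`.
#' @return Data frame with columns `x`, `mean`, `n`.
#' @export
moving_average <- function(x, y, window = 10, grid = NULL) {
  stopifnot(window > 0, length(x) == length(y))
  if (is.null(grid)) grid <- seq(floor(min(x)), ceiling(max(x)), by = 1)
  out <- lapply(grid, function(a) {
    sel <- x >= a - window / 2 & x < a + window / 2
    if (!any(sel)) return(NULL)
    data.frame(x = a, mean = mean(y[sel]), n = sum(sel))
  })
  do.call(rbind, out)
}
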
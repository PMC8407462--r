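# Independent oracles used to verify the package's implementations.
# These deliberately use naive algorithms distinct from the code paths
# they check.

# Descendant tip labels of the child node of each edge, by recursive
# adjacency traversal (independent of the postorder accumulation used in
# the package).
oracle_edge_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  descend <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], descend))
  }
  lapply(tree$edge[, 2], descend)
}

# Naive per-branch weighted UniFrac: explicit sum over every branch of
# length x |difference in descendant mass|.
oracle_weighted_unifrac <- function(tree, a, b) {
  tips <- oracle_edge_tips(tree)
  s <- 0
  for (i in seq_along(tips)) {
    pa <- sum(a[tips[[i]]])
    pb <- sum(b[tips[[i]]])
    s <- s + tree$edge.length[i] * abs(pa - pb)
  }
  s
}

# Brute-force BH step-up: q_i = min over j with p_(j) >= p_(i) of
# p_(j) * m / rank(j), evaluated from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[ord][i:m] * m / (i:m))
  }
  q_sorted <- pmin(1, q_sorted)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# PERMANOVA pseudo-F computed from scratch with explicit double loops.
oracle_permanova_F <- function(d, labels) {
  n <- nrow(d)
  g <- length(unique(labels))
  ss_t <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    s <- 0
    if (length(idx) > 1)
      for (i in seq_len(length(idx) - 1)) for (j in (i + 1):length(idx))
        s <- s + d[idx[i], idx[j]]^2
    ss_w <- ss_w + s / length(idx)
  }
  ((ss_t - ss_w) / (g - 1)) / (ss_w / (n - g))
}

# Exact permutation p by enumerating every permutation of the label
# vector with utils::combn over the positions of the first group
# (two-group case; each distinct assignment has equal multiplicity, so
# enumerating distinct assignments gives the same proportion).
oracle_permanova_exact_p <- function(d, labels) {
  n <- nrow(d)
  lev <- unique(labels)
  stopifnot(length(lev) == 2)
  k <- sum(labels == lev[1])
  F_obs <- oracle_permanova_F(d, labels)
  sets <- utils::combn(n, k)
  hits <- 0
  for (c in seq_len(ncol(sets))) {
    lab <- rep(lev[2], n)
    lab[sets[, c]] <- lev[1]
    if (oracle_permanova_F(d, lab) >= F_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(sets)
}

# Two-sided Fisher p for [[a,b],[c,d]] by enumerating all tables with
# the observed margins via factorial arithmetic.
oracle_fisher_p <- function(a, b, c, d) {
  lfac <- lfactorial
  tab_prob <- function(a2) {
    b2 <- a + b - a2; c2 <- a + c - a2; d2 <- d - a + a2
    if (min(b2, c2, d2) < 0) return(0)
    exp(lfac(a + b) + lfac(c + d) + lfac(a + c) + lfac(b + d) -
          lfac(a + b + c + d) - lfac(a2) - lfac(b2) - lfac(c2) - lfac(d2))
  }
  p_obs <- tab_prob(a)
  total <- 0
  for (a2 in 0:(a + b + c + d)) {
    pr <- tab_prob(a2)
    if (pr > 0 && pr <= p_obs * (1 + 1e-7)) total <- total + pr
  }
  total
}

# Upper-tail hypergeometric P(X >= k) by direct pmf summation.
oracle_hyper_upper <- function(N, K, n, k) {
  s <- 0
  for (x in k:min(K, n))
    s <- s + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  s
}

# RMS misfit of configuration Y against X after optimal translation,
# rotation and reflection (orthogonal Procrustes, no scaling).
oracle_procrustes_rms <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  if (ncol(Yc) < ncol(Xc))
    Yc <- cbind(Yc, matrix(0, nrow(Yc), ncol(Xc) - ncol(Yc)))
  if (ncol(Xc) < ncol(Yc))
    Xc <- cbind(Xc, matrix(0, nrow(Xc), ncol(Yc) - ncol(Xc)))
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  sqrt(mean((Yc %*% R - Xc)^2))
}

# Small fixture: a hand-built 4-tip tree with known branch lengths.
fixture_tree4 <- function() {
  ape::read.tree(text = "((t1:0.1,t2:0.2):0.3,(t3:0.4,t4:0.5):0.6);")
}

# Random rooted binary tree over n tips with uniform branch lengths,
# built with ape (independent of the package's generator).
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# A minimal taxonomy data frame for hand-built count fixtures.
fixture_taxonomy <- function(asv_ids, genus, phylum = NULL,
                             species = rep("", length(asv_ids))) {
  if (is.null(phylum)) phylum <- rep("Firmicutes", length(asv_ids))
  data.frame(asv_id = asv_ids, kingdom = "Bacteria", phylum = phylum,
             class = "", order = "", family = "", genus = genus,
             species = species, stringsAsFactors = FALSE)
}

# Hand-built gut_network object for cluster-extraction tests.
fixture_network <- function(edges, asv_ids, phylum, lowest_taxon,
                            total_count = NULL) {
  if (is.null(total_count)) total_count <- seq(1000, by = -10,
                                               length.out = length(asv_ids))
  nodes <- data.frame(asv_id = asv_ids, prevalence = 0.5,
                      total_count = total_count, phylum = phylum,
                      display_name = paste(lowest_taxon, "ASV"),
                      lowest_taxon = lowest_taxon, stringsAsFactors = FALSE)
  ne <- nrow(edges)
  ed <- data.frame(asv_a = as.character(edges[, 1]),
                   asv_b = as.character(edges[, 2]),
                   n_both = rep(50L, ne), fisher_p = rep(1e-9, ne),
                   fisher_q = rep(1e-8, ne), direction = rep("+", ne),
                   rho = rep(0.5, ne), rho_p = rep(1e-6, ne),
                   rho_q = rep(1e-5, ne), edge = rep(TRUE, ne),
                   stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = ed, tests = ed,
                 criterion_counts = c(cooccurrence = nrow(ed),
                                      quantitative = nrow(ed),
                                      edges = nrow(ed))),
            class = "gut_network")
}
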
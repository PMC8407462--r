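#' ASVs passing the prevalence filter
#'
#' @param counts Count matrix (samples x ASVs).
#' @param min_prev Minimum prevalence; ASVs observed in at least this
#'   proportion of samples (inclusive) are kept.
#' @return Character vector of eligible ASV ids.
#' @export
prevalence_filter <- function(counts, min_prev = 0.10) {
  stopifnot(min_prev > 0, min_prev <= 1)
  prev <- colMeans(counts > 0)
  colnames(counts)[prev >= min_prev]
}

# Two-sided Fisher exact p for the 2x2 table [[a, b], [c, d]] via direct
# enumeration of the hypergeometric pmf over all tables with the same
# margins (summing probabilities <= that of the observed table, the same
# rule fisher.test uses).
fisher_2x2_p <- function(a, b, c, d) {
  K <- a + b            # margin of taxon A
  n <- a + b + c + d
  k <- a + c            # margin of taxon B
  lo <- max(0, k - (n - K)); hi <- min(K, k)
  if (lo == hi) return(1)  # degenerate margin: single possible table
  probs <- stats::dhyper(lo:hi, K, n - K, k)
  p_obs <- stats::dhyper(a, K, n - K, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Cooccurrence test for a pair of ASVs
#'
#' Two-sided Fisher exact test on the 2x2 presence/absence table of two
#' ASVs (both observed / only one / neither). The direction is positive
#' when the observed number of joint occurrences exceeds its expectation
#' under independence.
#'
#' @param presence_a,presence_b Logical vectors over the same samples.
#' @return List with `table`, `p.value`, `direction` (`"+"`/`"-"`) and
#'   `flag` (`"zero-variance"` when one ASV is constant, in which case
#'   `p = 1`).
#' @export
cooccurrence_test <- function(presence_a, presence_b) {
  stopifnot(length(presence_a) == length(presence_b))
  n <- length(presence_a)
  n_both <- sum(presence_a & presence_b)
  n_a_only <- sum(presence_a & !presence_b)
  n_b_only <- sum(!presence_a & presence_b)
  n_neither <- n - n_both - n_a_only - n_b_only
  tab <- matrix(c(n_both, n_a_only, n_b_only, n_neither), 2, byrow = TRUE,
                dimnames = list(c("A+", "A-"), c("B+", "B-")))
  flag <- NULL
  if (all(presence_a) || all(!presence_a) || all(presence_b) || all(!presence_b)) {
    flag <- "zero-variance"
    p <- 1
  } else {
    p <- fisher_2x2_p(n_both, n_a_only, n_b_only, n_neither)
  }
  expected <- sum(presence_a) * sum(presence_b) / n
  list(table = tab, p.value = p,
       direction = if (n_both > expected) "+" else "-", flag = flag)
}

# Spearman rho with mid-rank ties plus its two-sided p from the
# t approximation t = rho * sqrt((n-2) / (1-rho^2)).
spearman_rho_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p.value = NA_real_))
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p.value = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p.value = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Quantitative association test for a pair of ASVs
#'
#' Spearman correlation between the log-transformed nonzero relative
#' abundances of two ASVs, computed only over samples where both are
#' observed. Pairs with fewer than `min_overlap` joint observations, or
#' with constant ranks on the overlap, are excluded (`NULL`).
#'
#' @param abund_a,abund_b Relative-abundance vectors over the same
#'   samples.
#' @param min_overlap Minimum number of jointly nonzero samples.
#' @return List with `rho`, `p.value`, `n_overlap`, or `NULL` when the
#'   pair is excluded.
#' @export
quantitative_test <- function(abund_a, abund_b, min_overlap = 10) {
  stopifnot(length(abund_a) == length(abund_b))
  sel <- abund_a > 0 & abund_b > 0
  if (sum(sel) < min_overlap) return(NULL)
  sp <- spearman_rho_p(log(abund_a[sel]), log(abund_b[sel]))
  if (is.na(sp$rho)) return(NULL)
  list(rho = sp$rho, p.value = sp$p.value, n_overlap = sum(sel))
}

#' Benjamini-Hochberg step-up false-discovery-rate control
#'
#' @param p Vector of p-values.
#' @param alpha FDR level for the rejection flags.
#' @return List with `q` (BH-adjusted q-values) and `reject`
#'   (`q < alpha`).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q < alpha)
}

#' Build the dual-criterion ASV association network
#'
#' ASVs passing the prevalence filter become nodes. Every pair is tested
#' for cooccurrence (Fisher exact on presence/absence) and for positive
#' quantitative association (Spearman on log nonzero abundances over the
#' joint-presence samples). BH correction is applied separately within
#' each test family; an edge requires, by default, a positively directed
#' Fisher q below `fdr_cooc` AND a positive rho with q below
#' `fdr_quant`. With `rule = "union"` either criterion suffices.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param tax Taxonomy data frame (with display names, see
#'   [assign_display_names()]).
#' @param fdr_cooc,fdr_quant FDR thresholds of the two criteria.
#' @param min_prev Prevalence filter.
#' @param min_overlap Minimum joint-presence count for the quantitative
#'   test.
#' @param rule `"intersection"` (default) or `"union"`.
#' @return A `gut_network` list: `nodes`, `edges`, `tests` (all pair
#'   tests), and `criterion_counts` (pairs passing each criterion
#'   separately).
#' @export
build_network <- function(counts, tax, fdr_cooc = 1e-6, fdr_quant = 1e-3,
                          min_prev = 0.10, min_overlap = 10,
                          rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  eligible <- prevalence_filter(counts, min_prev)
  if (length(eligible) < 2) stop("fewer than 2 ASVs pass the prevalence filter")
  sub <- counts[, eligible, drop = FALSE]
  rel <- sub / rowSums(counts)  # relative to full library size
  P <- sub > 0
  n <- nrow(sub); E <- ncol(sub)
  K <- colSums(P)
  Nboth <- crossprod(P * 1)  # joint presence counts for all pairs
  pairs <- which(upper.tri(Nboth), arr.ind = TRUE)
  n_pairs <- nrow(pairs)
  fisher_p <- direction <- numeric(n_pairs)
  rho <- rho_p <- rep(NA_real_, n_pairs)
  n_overlap <- integer(n_pairs)
  for (t in seq_len(n_pairs)) {
    i <- pairs[t, 1]; j <- pairs[t, 2]
    nb <- Nboth[i, j]
    na_only <- K[i] - nb; nb_only <- K[j] - nb
    nn <- n - nb - na_only - nb_only
    if (K[i] == 0 || K[i] == n || K[j] == 0 || K[j] == n) {
      fisher_p[t] <- 1
    } else {
      fisher_p[t] <- fisher_2x2_p(nb, na_only, nb_only, nn)
    }
    direction[t] <- nb - K[i] * K[j] / n
    n_overlap[t] <- nb
    if (nb >= min_overlap) {
      sel <- P[, i] & P[, j]
      sp <- spearman_rho_p(log(rel[sel, i]), log(rel[sel, j]))
      rho[t] <- sp$rho; rho_p[t] <- sp$p.value
    }
  }
  fisher_q <- stats::p.adjust(fisher_p, method = "BH")
  rho_q <- rep(NA_real_, n_pairs)
  tested <- !is.na(rho_p)
  rho_q[tested] <- stats::p.adjust(rho_p[tested], method = "BH")
  pass_cooc <- fisher_q < fdr_cooc & direction > 0
  pass_quant <- tested & !is.na(rho) & rho > 0 & rho_q < fdr_quant
  is_edge <- if (rule == "intersection") pass_cooc & pass_quant
             else pass_cooc | pass_quant
  tests <- data.frame(
    asv_a = eligible[pairs[, 1]], asv_b = eligible[pairs[, 2]],
    n_both = n_overlap, fisher_p = fisher_p, fisher_q = fisher_q,
    direction = ifelse(direction > 0, "+", "-"),
    rho = rho, rho_p = rho_p, rho_q = rho_q,
    edge = is_edge, stringsAsFactors = FALSE)
  tax_sub <- tax[match(eligible, tax$asv_id), , drop = FALSE]
  nodes <- data.frame(
    asv_id = eligible,
    prevalence = unname(colMeans(P)),
    total_count = unname(colSums(sub)),
    phylum = tax_sub$phylum,
    display_name = if ("display_name" %in% colnames(tax_sub))
      tax_sub$display_name else tax_sub$asv_id,
    lowest_taxon = if ("lowest_taxon" %in% colnames(tax_sub))
      tax_sub$lowest_taxon else tax_sub$genus,
    stringsAsFactors = FALSE)
  structure(list(
    nodes = nodes,
    edges = tests[is_edge, , drop = FALSE],
    tests = tests,
    criterion_counts = c(cooccurrence = sum(pass_cooc),
                         quantitative = sum(pass_quant),
                         edges = sum(is_edge))),
    class = "gut_network")
}

#' Extract microbial clusters from the association network
#'
#' Implements the clique-based cluster definition: (1) all 3-cliques are
#' enumerated; (2) cliques sharing a node are merged into groups
#' (equivalently, connected components of the subgraph restricted to
#' edges belonging to at least one triangle); (3) each group is split
#' into phylum-consistent subgroups (connected components of the
#' same-phylum induced subgraphs); (4) remaining network nodes adjacent
#' to a subgroup member with an identical lowest-taxon label are
#' attached (to the first qualifying subgroup, iterated to a fixed
#' point); (5) each cluster is named after the display taxon of its
#' highest-total-count member, with `C1`, `C2`, ... suffixes
#' disambiguating clusters sharing a name. Clusters with fewer than 3
#' members are dropped.
#'
#' @param net A `gut_network` from [build_network()].
#' @return Data frame with columns `cluster` (id), `member` (ASV id),
#'   `phylum` (dominant phylum of the cluster), `name`.
#' @export
find_clusters <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (nrow(edges) == 0)
    return(data.frame(cluster = character(), member = character(),
                      phylum = character(), name = character(),
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges[, c("asv_a", "asv_b")],
                                     directed = FALSE,
                                     vertices = nodes$asv_id)
  # (1)+(2): edges in >= 1 triangle, then connected components
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  in_tri <- vapply(seq_len(nrow(el)), function(k)
    any(adj[el[k, 1], ] & adj[el[k, 2], ]), logical(1))
  if (!any(in_tri))
    return(data.frame(cluster = character(), member = character(),
                      phylum = character(), name = character(),
                      stringsAsFactors = FALSE))
  g_tri <- igraph::subgraph_from_edges(g, which(in_tri), delete.vertices = FALSE)
  comp <- igraph::components(g_tri)
  deg_tri <- igraph::degree(g_tri)
  phylum_of <- stats::setNames(nodes$phylum, nodes$asv_id)
  taxon_of <- stats::setNames(nodes$lowest_taxon, nodes$asv_id)
  total_of <- stats::setNames(nodes$total_count, nodes$asv_id)
  vnames <- igraph::V(g)$name
  subgroups <- list()
  for (cid in seq_len(comp$no)) {
    members <- vnames[comp$membership == cid & deg_tri > 0]
    if (length(members) < 3) next
    # (3): split by phylum, components within same-phylum subgraph
    for (ph in unique(phylum_of[members])) {
      ms <- members[phylum_of[members] == ph]
      sg <- igraph::induced_subgraph(g, ms)
      sc <- igraph::components(sg)
      for (k in seq_len(sc$no))
        subgroups[[length(subgroups) + 1]] <-
          igraph::V(sg)$name[sc$membership == k]
    }
  }
  if (length(subgroups) == 0)
    return(data.frame(cluster = character(), member = character(),
                      phylum = character(), name = character(),
                      stringsAsFactors = FALSE))
  # (4): absorb same-taxon neighbours, iterated to a fixed point
  assigned <- unlist(subgroups)
  repeat {
    changed <- FALSE
    for (si in seq_along(subgroups)) {
      mem <- subgroups[[si]]
      nb <- unique(vnames[unlist(igraph::adjacent_vertices(
        g, mem))])
      cand <- setdiff(nb, assigned)
      if (!length(cand)) next
      take <- vapply(cand, function(v) {
        adjv <- vnames[igraph::neighbors(g, v)]
        any(taxon_of[intersect(adjv, mem)] == taxon_of[v])
      }, logical(1))
      if (any(take)) {
        subgroups[[si]] <- c(mem, cand[take])
        assigned <- c(assigned, cand[take])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  subgroups <- Filter(function(m) length(m) >= 3, subgroups)
  if (!length(subgroups))
    return(data.frame(cluster = character(), member = character(),
                      phylum = character(), name = character(),
                      stringsAsFactors = FALSE))
  # (5): order by cluster mass, name after the most abundant member
  mass <- vapply(subgroups, function(m) sum(total_of[m]), numeric(1))
  subgroups <- subgroups[order(-mass)]
  base_names <- vapply(subgroups, function(m)
    unname(taxon_of[m[which.max(total_of[m])]]), character(1))
  name_final <- base_names
  for (nm in unique(base_names)) {
    idx <- which(base_names == nm)
    if (length(idx) > 1)
      name_final[idx] <- paste0(nm, " C", seq_along(idx))
  }
  out <- do.call(rbind, lapply(seq_along(subgroups), function(i) {
    mem <- sort(subgroups[[i]])
    ph <- names(which.max(table(phylum_of[mem])))
    data.frame(cluster = sprintf("MC%02d", i), member = mem, phylum = ph,
               name = name_final[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Negatively associated ASV pairs
#'
#' Same quantitative machinery as [build_network()], restricted to
#' negative Spearman correlations, with BH correction within the
#' negative family. Never part of clusters; returned as a separate edge
#' list.
#'
#' @inheritParams build_network
#' @param fdr FDR threshold.
#' @return Data frame of significantly negative pairs.
#' @export
negative_associations <- function(counts, fdr = 1e-3, min_prev = 0.10,
                                  min_overlap = 10) {
  eligible <- prevalence_filter(counts, min_prev)
  sub <- counts[, eligible, drop = FALSE]
  rel <- sub / rowSums(counts)
  P <- sub > 0
  pairs <- utils::combn(length(eligible), 2)
  res <- lapply(seq_len(ncol(pairs)), function(t) {
    i <- pairs[1, t]; j <- pairs[2, t]
    sel <- P[, i] & P[, j]
    if (sum(sel) < min_overlap) return(NULL)
    sp <- spearman_rho_p(log(rel[sel, i]), log(rel[sel, j]))
    if (is.na(sp$rho) || sp$rho >= 0) return(NULL)
    data.frame(asv_a = eligible[i], asv_b = eligible[j], rho = sp$rho,
               rho_p = sp$p.value, n_overlap = sum(sel),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(asv_a = character(), asv_b = character(),
                      rho = numeric(), rho_p = numeric(),
                      rho_q = numeric(), n_overlap = integer(),
                      stringsAsFactors = FALSE))
  res$rho_q <- stats::p.adjust(res$rho_p, method = "BH")
  res[res$rho_q < fdr, , drop = FALSE]
}
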
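test_that("prevalence filter uses an inclusive threshold", {
  counts <- matrix(0L, 100, 3, dimnames = list(paste0("s", 1:100),
                                               c("rare", "edge", "common")))
  counts[1:9, "rare"] <- 1L
  counts[1:10, "edge"] <- 1L
  counts[, "common"] <- 1L
  keep <- prevalence_filter(counts, 0.10)
  expect_false("rare" %in% keep)     # 0.09 < 0.10
  expect_true("edge" %in% keep)      # 0.10 >= 0.10
  expect_equal(prevalence_filter(counts, 1.0), "common")
  expect_error(prevalence_filter(counts, 0), "min_prev")
})

test_that("cooccurrence test matches enumeration and flags degeneracy", {
  # [[5,0],[0,5]]: p = 2/252
  a <- rep(c(TRUE, FALSE), each = 5)
  res <- cooccurrence_test(a, a)
  expect_equal(res$p.value, 2 / 252, tolerance = 1e-12)
  expect_equal(res$direction, "+")
  # [[1,1],[1,1]]: independence, p = 1
  res2 <- cooccurrence_test(c(TRUE, TRUE, FALSE, FALSE),
                            c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res2$p.value, 1)
  # [[3,1],[1,3]]: p = 34/70
  a3 <- rep(c(TRUE, FALSE), each = 4)
  b3 <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(cooccurrence_test(a3, b3)$p.value, 34 / 70, tolerance = 1e-12)
  # constant vector flagged with p = 1
  res4 <- cooccurrence_test(rep(TRUE, 8), b3)
  expect_equal(res4$flag, "zero-variance")
  expect_equal(res4$p.value, 1)
})

test_that("Fisher p equals fisher.test and the enumeration oracle", {
  set.seed(6)
  for (r in 1:25) {
    tab <- matrix(rpois(4, 8), 2)
    p_pkg <- fisher_2x2_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p_pkg, fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(p_pkg, oracle_fisher_p(tab[1, 1], tab[1, 2],
                                        tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
})

test_that("quantitative test computes Spearman rho with exclusions", {
  x <- (1:20) / 100; y <- x^2  # monotone
  expect_equal(quantitative_test(x, y)$rho, 1)
  # hand-computed rho = 1 - 6*4/120 = 0.8
  xa <- c(0.01, 0.02, 0.03, 0.04, 0.05, rep(0, 5))
  yb <- c(0.02, 0.01, 0.04, 0.03, 0.05, rep(0, 5))
  res <- quantitative_test(xa, yb, min_overlap = 5)
  expect_equal(res$rho, 0.8, tolerance = 1e-12)
  expect_equal(res$n_overlap, 5)
  # overlap below threshold excluded
  expect_null(quantitative_test(c(0.1, 0.2, 0.3, 0, 0),
                                c(0.1, 0.2, 0.3, 0, 0), min_overlap = 10))
  # p agrees with cor.test's t approximation
  set.seed(3)
  u <- runif(30); v <- u + rnorm(30, 0, 0.3)
  res2 <- quantitative_test(u, v, min_overlap = 10)
  ct <- suppressWarnings(cor.test(log(u), log(v), method = "spearman",
                                  exact = FALSE))
  expect_equal(res2$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res2$p.value, ct$p.value, tolerance = 1e-9)
})

test_that("BH q-values equal the step-up definition", {
  expect_equal(bh_fdr(0.01)$q, 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.5))$q, c(0.01, 0.5))
  set.seed(11)
  for (r in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p)$q, oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "p")
})

test_that("the dual-criterion network recovers planted blocks only", {
  co <- generate_cohort(cohort_spec(n_samples = 400, n_asvs = 60,
                                    n_clusters = 3, cluster_size = 4,
                                    seed = 5))
  net <- build_network(co$counts, co$taxonomy)
  gt <- co$ground_truth$cluster_membership
  in_block <- !is.na(gt[net$edges$asv_a]) & !is.na(gt[net$edges$asv_b])
  same_block <- in_block & gt[net$edges$asv_a] == gt[net$edges$asv_b]
  # every edge touching a block stays within one block
  expect_true(all(same_block == in_block))
  # each block contributes enough edges to form a 3-clique
  cl <- find_clusters(net)
  recovered <- unique(cl$cluster)
  expect_gte(length(recovered), 3)
  # edges invariant under sample and ASV reordering
  set.seed(8)
  sp <- sample(nrow(co$counts)); ap <- sample(ncol(co$counts))
  net2 <- build_network(co$counts[sp, ap], co$taxonomy)
  key <- function(e) sort(paste(pmin(e$asv_a, e$asv_b),
                                pmax(e$asv_a, e$asv_b)))
  expect_equal(key(net2$edges), key(net$edges))
})

test_that("negative correlation never makes an edge", {
  set.seed(2)
  n <- 200
  base <- matrix(rpois(n * 3, 40), n, 3)
  x <- rpois(n, 30) + round(30 * exp(rnorm(n, 0, 0.5)))
  y <- round(2000 / (x + 10)) + rpois(n, 3)
  counts <- cbind(base, x, y)
  dimnames(counts) <- list(paste0("s", 1:n), paste0("a", 1:5))
  storage.mode(counts) <- "integer"
  tax <- fixture_taxonomy(colnames(counts), genus = rep("Blautia", 5))
  tax <- assign_display_names(counts, tax)
  net <- build_network(counts, tax, fdr_cooc = 0.5, fdr_quant = 0.5)
  pair <- net$tests[net$tests$asv_a == "a4" & net$tests$asv_b == "a5", ]
  expect_lt(pair$rho, 0)
  expect_false(pair$edge)
})

test_that("null data yield essentially no edges at the strict thresholds", {
  set.seed(14)
  false_edges <- 0
  for (r in 1:10) {
    counts <- matrix(rbinom(150 * 20, 60, 0.25), 150, 20)
    counts[runif(length(counts)) < 0.4] <- 0L
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(paste0("s", 1:150), paste0("a", 1:20))
    counts[, 1] <- counts[, 1] + 1L  # keep row sums positive
    tax <- fixture_taxonomy(colnames(counts), genus = rep("Dorea", 20))
    net <- build_network(counts, tax)
    false_edges <- false_edges + nrow(net$edges)
  }
  expect_lte(false_edges, 1)
})

test_that("cluster extraction follows the clique/split/join rules", {
  # single triangle, one phylum -> one cluster named after largest member
  net <- fixture_network(cbind(c("a", "b", "c"), c("b", "c", "a")),
                         asv_ids = c("a", "b", "c"),
                         phylum = rep("Firmicutes", 3),
                         lowest_taxon = c("Blautia", "Dorea", "Dorea"),
                         total_count = c(900, 100, 50))
  cl <- find_clusters(net)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_setequal(cl$member, c("a", "b", "c"))
  expect_equal(unique(cl$name), "Blautia")
  expect_equal(unique(cl$phylum), "Firmicutes")

  # two triangles sharing a node, different phyla -> split by phylum;
  # the 3-member phylum-A side survives, the 2-member remainder drops
  ids <- c("a1", "a2", "a3", "b1", "b2")
  edges <- rbind(c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
                 c("a3", "b1"), c("a3", "b2"), c("b1", "b2"))
  net2 <- fixture_network(edges, ids,
                          phylum = c("Bacteroidetes", "Bacteroidetes",
                                     "Bacteroidetes", "Firmicutes",
                                     "Firmicutes"),
                          lowest_taxon = c("Bacteroides", "Bacteroides",
                                           "Bacteroides", "Blautia",
                                           "Blautia"))
  cl2 <- find_clusters(net2)
  expect_equal(length(unique(cl2$cluster)), 1)
  expect_setequal(cl2$member, c("a1", "a2", "a3"))

  # pendant node with matching lowest taxon is absorbed
  ids3 <- c("a", "b", "c", "p")
  edges3 <- rbind(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "p"))
  net3 <- fixture_network(edges3, ids3, phylum = rep("Firmicutes", 4),
                          lowest_taxon = c("Dorea", "Dorea", "Dorea",
                                           "Dorea"))
  cl3 <- find_clusters(net3)
  expect_true("p" %in% cl3$member)
  # but not when its taxon differs
  net4 <- fixture_network(edges3, ids3, phylum = rep("Firmicutes", 4),
                          lowest_taxon = c("Dorea", "Dorea", "Dorea",
                                           "Blautia"))
  cl4 <- find_clusters(net4)
  expect_false("p" %in% cl4$member)
  # empty network -> empty cluster table
  empty <- fixture_network(cbind(character(0), character(0)),
                           asv_ids = "a", phylum = "Firmicutes",
                           lowest_taxon = "Dorea")
  expect_equal(nrow(find_clusters(empty)), 0)
})

test_that("negative association screen finds planted anticorrelation only", {
  co <- generate_cohort(cohort_spec(n_samples = 400, n_asvs = 60,
                                    n_clusters = 2, cluster_size = 4,
                                    seed = 9))
  neg <- negative_associations(co$counts)
  expect_gt(nrow(neg), 0)
  gen <- function(a) co$taxonomy$genus[match(a, co$taxonomy$asv_id)]
  bp <- (gen(neg$asv_a) == "Bacteroides" & gen(neg$asv_b) == "Prevotella") |
    (gen(neg$asv_a) == "Prevotella" & gen(neg$asv_b) == "Bacteroides")
  # the planted enterotype structure makes Bacteroides-Prevotella the
  # dominant anticorrelated pair type
  expect_gt(mean(bp), 0.5)
  expect_gt(sum(bp), 10)
  expect_true(all(neg$rho < 0))
  # a strongly positive pair never appears in the negative list
  gt <- co$ground_truth$cluster_membership
  b1 <- names(gt)[!is.na(gt) & gt == 1][1:2]
  expect_false(any(neg$asv_a %in% b1 & neg$asv_b %in% b1))
})
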
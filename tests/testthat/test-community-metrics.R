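test_that("relative abundance normalises rows and aggregates by rank", {
  counts <- matrix(c(10L, 30L, 60L), 1, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(relative_abundance(counts)["s1", ]), c(0.10, 0.30, 0.60))
  one <- matrix(5L, 1, dimnames = list("s1", "a"))
  expect_equal(unname(relative_abundance(one)[1, 1]), 1.0)
  # two ASVs of one genus, counts 10 + 20 of a 100-read sample -> 0.30
  counts2 <- matrix(c(10L, 20L, 70L), 1,
                    dimnames = list("s1", c("a", "b", "c")))
  tax <- fixture_taxonomy(c("a", "b", "c"),
                          genus = c("Blautia", "Blautia", "Dorea"))
  ra <- relative_abundance(counts2, tax, "genus")
  expect_equal(unname(ra["s1", "Blautia"]), 0.30)
  expect_error(relative_abundance(rbind(counts2, s2 = c(0L, 0L, 0L))), "zero")
  # rows always sum to 1
  co <- generate_cohort(cohort_spec(n_samples = 12, n_asvs = 50,
                                    n_clusters = 1, cluster_size = 3, seed = 2))
  for (lv in c("ASV", "genus", "phylum"))
    expect_equal(unname(rowSums(relative_abundance(co$counts, co$taxonomy, lv))),
                 rep(1, 12), tolerance = 1e-12)
})

test_that("prevalence counts nonzero samples, with union rule at genus level", {
  counts <- matrix(c(1L, 2L, 3L, 4L, 0L,  0L, 0L, 0L, 0L, 0L), ncol = 2,
                   dimnames = list(paste0("s", 1:5), c("a", "b")))
  p <- prevalence(counts)
  expect_equal(unname(p["a"]), 0.8)
  expect_equal(unname(p["b"]), 0.0)
  # genus prevalence = presence of any member ASV, against brute force
  set.seed(42)
  counts2 <- matrix(rbinom(60, 1, 0.4) * 5L, nrow = 10)
  dimnames(counts2) <- list(paste0("s", 1:10), paste0("a", 1:6))
  tax <- fixture_taxonomy(colnames(counts2),
                          genus = rep(c("g1", "g2", "g3"), each = 2))
  pg <- prevalence(counts2, tax, "genus")
  for (g in c("g1", "g2", "g3")) {
    members <- tax$asv_id[tax$genus == g]
    manual <- mean(apply(counts2[, members] > 0, 1, any))
    expect_equal(unname(pg[g]), manual)
  }
})

test_that("observed richness counts nonzero ASVs and ignores scaling", {
  counts <- matrix(c(5L, 0L, 2L), 1, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(observed_richness(counts)), 2L)
  expect_equal(unname(observed_richness(counts * 10L)),
               unname(observed_richness(counts)))
  zero <- matrix(0L, 1, 3, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(observed_richness(zero)), 0L)
})

test_that("weighted UniFrac matches hand-computed and oracle values", {
  # identical communities
  tr <- fixture_tree4()
  a <- c(t1 = 0.25, t2 = 0.25, t3 = 0.25, t4 = 0.25)
  expect_equal(weighted_unifrac(tr, a, a), 0)
  # two-leaf tree, unit branch lengths, opposite point masses -> 2
  tr2 <- ape::read.tree(text = "(x:1,y:1);")
  expect_equal(weighted_unifrac(tr2, c(x = 1, y = 0), c(x = 0, y = 1)), 2.0)
  # random trees and abundances vs the naive per-branch oracle
  for (r in 1:20) {
    tr3 <- random_tree(8, seed = 100 + r)
    set.seed(200 + r)
    a3 <- stats::setNames(rdiff <- {x <- runif(8); x / sum(x)}, tr3$tip.label)
    b3 <- stats::setNames({y <- runif(8); y / sum(y)}, tr3$tip.label)
    expect_equal(weighted_unifrac(tr3, a3, b3),
                 oracle_weighted_unifrac(tr3, a3, b3), tolerance = 1e-12)
  }
  expect_error(weighted_unifrac(tr2, c(x = 1, z = 0), c(x = 0, z = 1)),
               "absent")
})

test_that("weighted UniFrac is a metric on random instances", {
  tr <- random_tree(10, seed = 7)
  set.seed(8)
  comm <- t(replicate(6, {x <- rgamma(10, 0.5); x / sum(x)}))
  colnames(comm) <- tr$tip.label
  rownames(comm) <- paste0("s", 1:6)
  d <- unifrac_matrix(tr, comm)
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
})

test_that("the distance matrix equals pairwise single calls", {
  tr <- random_tree(6, seed = 3)
  set.seed(4)
  comm <- t(replicate(3, {x <- runif(6); x / sum(x)}))
  colnames(comm) <- tr$tip.label
  rownames(comm) <- paste0("s", 1:3)
  d <- unifrac_matrix(tr, comm)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(d[i, j], weighted_unifrac(tr, comm[i, ], comm[j, ]),
                 tolerance = 1e-12)
  dup <- unifrac_matrix(tr, comm[c(1, 1), ])
  expect_equal(dup[1, 2], 0)
})

test_that("PCoA reproduces known configurations", {
  # two samples at distance d -> coordinates +/- d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord2 <- pcoa_ordination(d2, 1)
  expect_equal(unname(sort(ord2$coordinates[, 1])), c(-1.5, 1.5))
  # planar points recovered up to rotation/reflection
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(X))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  ord <- pcoa_ordination(d, 2)
  expect_lt(oracle_procrustes_rms(X, ord$coordinates), 1e-8)
  # with all axes kept, pairwise distances are reproduced
  ordf <- pcoa_ordination(d, 19)
  expect_equal(as.matrix(dist(ordf$coordinates)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))
  expect_true(all(ord$proportion_explained >= 0 &
                    ord$proportion_explained <= 1))
  # degenerate all-zero distances
  dz <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(pcoa_ordination(dz, 2)$coordinates == 0))
  expect_error(pcoa_ordination(d[, 1:3], 2), "square")
  expect_error(pcoa_ordination(d2, 5), "n_axes")
})

test_that("moving averages behave on constant, single and linear input", {
  ages <- c(30, 40, 50, 60)
  expect_equal(unique(moving_average(ages, rep(7, 4), window = 50)$mean), 7)
  one <- moving_average(55, 3.5, window = 10)
  expect_equal(one$mean[one$x == 55], 3.5)
  # linear y over a symmetric window has no bias at interior grid points
  set.seed(1)
  x <- runif(4000, 20, 80)
  y <- 2 * x + 5
  ma <- moving_average(x, y, window = 10, grid = seq(30, 70, by = 5))
  expect_lt(max(abs(ma$mean - (2 * ma$x + 5))), 0.6)
  expect_error(moving_average(1, 1, window = 0), "window")
})
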
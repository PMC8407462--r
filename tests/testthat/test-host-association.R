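test_that("hypergeometric screen matches direct pmf summation", {
  pres <- matrix(c(rep(TRUE, 10), rep(FALSE, 10)), ncol = 1,
                 dimnames = list(NULL, "asv"))
  groups <- rep(c("g1", "g2"), each = 5, length.out = 20)
  # N=20, K=10, n=5 per group; construct k=5 in g1
  pres[] <- FALSE; pres[c(1:5, 11:15), 1] <- TRUE
  grp <- c(rep("g1", 5), rep("rest", 15))
  res <- prevalence_enrichment(pres, grp, alpha = 0.1)
  row <- res[res$group == "g1", ]
  expect_equal(row$k, 5)
  expect_equal(row$p_enriched, 252 / 15504, tolerance = 1e-12)
  expect_equal(row$p_enriched, oracle_hyper_upper(20, 10, 5, 5),
               tolerance = 1e-12)
  expect_equal(row$direction, "+")
  # k at its expectation: both tails above 0.5, no call
  set.seed(2)
  pres2 <- matrix(FALSE, 100, 1, dimnames = list(NULL, "asv"))
  pres2[1:50, 1] <- TRUE
  grp2 <- rep("rest", 100); grp2[c(1:5, 51:55)] <- "g"  # k = 5 of n = 10
  res2 <- prevalence_enrichment(pres2, grp2, alpha = 0.1)
  row2 <- res2[res2$group == "g", ]
  expect_gt(row2$p_enriched, 0.5)
  expect_gt(row2$p_depleted, 0.5)
  expect_false(row2$significant)
  # ubiquitous taxon: k = n always, enrichment p = 1
  pres3 <- matrix(TRUE, 30, 1, dimnames = list(NULL, "asv"))
  res3 <- prevalence_enrichment(pres3, rep(c("a", "b"), 15), alpha = 0.1)
  expect_true(all(res3$p_enriched == 1))
  expect_error(prevalence_enrichment(pres3, factor(rep("a", 30),
                                                   levels = c("a", "b"))),
               "empty")
})

test_that("hypergeometric pmf sums to one over its support", {
  for (pars in list(c(20, 10, 5), c(100, 37, 12), c(15, 15, 7))) {
    N <- pars[1]; K <- pars[2]; n <- pars[3]
    k <- max(0, n + K - N):min(K, n)
    expect_equal(sum(dhyper(k, K, N - K, n)), 1, tolerance = 1e-12)
  }
})

test_that("IQR winsorisation clips exactly at the type-7 cutoffs", {
  expect_equal(winsorize_iqr(1:9), 1:9)
  x <- c(1:9, 100)
  out <- winsorize_iqr(x)
  expect_equal(out[10], 14.5)   # Q1=3.25, Q3=7.75, IQR=4.5
  expect_equal(out[1:9], 1:9)
  expect_equal(winsorize_iqr(rep(5, 6)), rep(5, 6))
  # idempotent
  set.seed(4)
  y <- rcauchy(100)
  expect_equal(winsorize_iqr(winsorize_iqr(y)), winsorize_iqr(y))
  expect_error(winsorize_iqr("a"), "numeric")
  expect_error(winsorize_iqr(c(1, 2, 3)), "at least 4")
})

test_that("associate recovers exact and simulated effects", {
  set.seed(5)
  ab <- runif(10, 0.01, 0.2)
  y <- 2 * log_abundance(ab)
  res <- suppressWarnings(associate(ab, y, age = NULL))
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_lt(res$p.value, 1e-12)
  expect_false(res$age_adjusted)
  # F equals squared t for single-predictor fits
  for (r in 1:10) {
    set.seed(100 + r)
    ab2 <- runif(30, 0.001, 0.3)
    y2 <- rnorm(30)
    r2 <- associate(ab2, y2, age = NULL)
    fit <- lm(y2 ~ log_abundance(ab2))
    expect_equal(r2$F, summary(fit)$coefficients[2, "t value"]^2,
                 tolerance = 1e-10)
  }
  # exclusions
  expect_null(associate(rep(0, 20), rnorm(20)))
  expect_null(associate(runif(20), rep(1, 20)))
  expect_null(associate(runif(8), rnorm(8)))
})

test_that("slope estimates are unbiased with nominal CI coverage", {
  set.seed(6)
  n <- 500
  betas <- covered <- numeric(500)
  for (r in 1:500) {
    x <- log(runif(n, 1e-4, 1e-1))
    y <- 0.5 * x + rnorm(n, 0, 1)
    fit <- lm(y ~ x)
    betas[r] <- coef(fit)[2]
    ci <- confint(fit)[2, ]
    covered[r] <- ci[1] <= 0.5 && 0.5 <= ci[2]
  }
  expect_lt(abs(mean(betas) - 0.5), 0.05)
  expect_lt(abs(mean(covered) - 0.95), 0.03)
})

test_that("age conditioning triggers exactly when age wins the univariate fit", {
  set.seed(7)
  n <- 200
  ab <- runif(n, 0.001, 0.2)
  x <- log_abundance(ab)
  age <- 50 + 5 * scale(x)[, 1] + rnorm(n, 0, 1)    # age strongly tied to x
  y <- 0.3 * x + 0.2 * age + rnorm(n)
  res <- associate(ab, y, age = age)
  expect_true(res$age_adjusted)
  fit2 <- lm(y ~ x + age)
  expect_equal(res$beta, coef(fit2)[["x"]], tolerance = 1e-10)
  # and not when the factor wins
  y2 <- 3 * x + rnorm(n, 0, 0.5)
  age2 <- rnorm(n, 50, 10)
  expect_false(associate(ab, y2, age = age2)$age_adjusted)
})

test_that("associate_all controls the FDR and finds stratified effects", {
  female_eff <- data.frame(asv = "block1_1", factor = "bmi", beta = 0.8,
                           direction = "+", stratum = "female")
  co <- generate_cohort(cohort_spec(n_samples = 400, n_asvs = 60,
                                    n_clusters = 2, cluster_size = 4,
                                    et_proportions = c(1, 0),
                                    effect_table = female_eff, seed = 12))
  eff_asv <- co$ground_truth$planted_effects$asv_id
  is_f <- co$metadata$sex == "female"
  af <- associate_all(co$counts[is_f, ], co$metadata[is_f, ],
                      factors = "bmi", fdr = 0.2)
  am <- associate_all(co$counts[!is_f, ], co$metadata[!is_f, ],
                      factors = "bmi", fdr = 0.2)
  expect_true(af$significant[af$asv_id == eff_asv])
  expect_false(am$significant[am$asv_id == eff_asv])
})

test_that("diet PCA recovers planted axes and dominant variance", {
  set.seed(8)
  n <- 300
  # a latent factor loads strongly on f3, weakly on f4/f5: after
  # standardisation PC1 concentrates on f3
  lat <- rnorm(n)
  one <- matrix(rnorm(n * 5), n, 5)
  one[, 3] <- lat + 0.2 * rnorm(n)
  one[, 4] <- 0.5 * lat + rnorm(n)
  one[, 5] <- 0.5 * lat + rnorm(n)
  colnames(one) <- paste0("f", 1:5)
  dp <- diet_pca(one)
  expect_equal(which.max(abs(dp$loadings[, 1])), 3L, ignore_attr = TRUE)
  expect_equal(sum(dp$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(dp$variance_explained) <= 1e-12))
  # planted two-factor structure: leading 2 PCs span the planted
  # subspace (compared in the standardised coordinates the PCA sees)
  a1 <- rnorm(n); a2 <- rnorm(n)
  L <- matrix(rnorm(17 * 2), 17, 2)
  X <- cbind(a1, a2) %*% t(L) + matrix(rnorm(n * 17, sd = 0.3), n, 17)
  colnames(X) <- paste0("g", 1:17)
  dp2 <- diet_pca(X)
  L_std <- L / apply(X, 2, sd)
  Q1 <- qr.Q(qr(L_std))
  Q2 <- qr.Q(qr(dp2$loadings[, 1:2]))
  ang <- acos(min(c(svd(crossprod(Q1, Q2))$d, 1))) * 180 / pi
  expect_lt(ang, 5)
  # orientation rule: largest-magnitude loading positive
  expect_true(all(apply(dp2$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  X2 <- cbind(X, const = 1)
  expect_warning(diet_pca(X2), "constant")
})

test_that("age-diversity correlation is computed per sex stratum", {
  set.seed(9)
  n <- 300
  age <- runif(n, 20, 80)
  sex <- rep(c("female", "male"), length.out = n)
  rich <- as.integer(round(50 + 0.5 * age + rnorm(n, 0, 5)))
  res <- age_diversity_correlation(rich, age, sex)
  expect_setequal(res$stratum, c("female", "male", "all"))
  expect_true(all(res$rho > 0))
  expect_true(all(res$p < 0.05))
  # strictly monotone -> rho = 1
  res2 <- age_diversity_correlation(seq_len(20), seq_len(20),
                                    rep("female", 20))
  expect_equal(res2$rho[res2$stratum == "female"], 1)
  expect_error(age_diversity_correlation(rich[1:5], age[1:5], sex[1:5]),
               "fewer than 10")
})

test_that("age-abundance screen detects planted trends, rank-invariantly", {
  set.seed(10)
  n <- 300
  age <- runif(n, 20, 80)
  counts <- matrix(rpois(n * 10, 50), n, 10)
  # ASV 1 abundance increases with age
  counts[, 1] <- rpois(n, 20 * exp(0.03 * (age - 50)))
  dimnames(counts) <- list(paste0("s", 1:n), paste0("a", 1:10))
  storage.mode(counts) <- "integer"
  res <- age_abundance_correlation(counts, age, fdr = 0.2)
  expect_true(res$significant[res$asv_id == "a1"])
  expect_gt(res$rho[res$asv_id == "a1"], 0)
  # any other call is the compositional shadow of the planted trend
  # (relative abundances of unaffected ASVs shrink as a1 grows)
  expect_true(all(res$rho[res$significant & res$asv_id != "a1"] < 0))
  # a trend-free table yields at most the odd FDR-level false call
  null_counts <- counts[, -1]
  res0 <- age_abundance_correlation(null_counts, age, fdr = 0.2)
  expect_lte(sum(res0$significant), 1)
  # monotone transform of age leaves rho unchanged
  res2 <- age_abundance_correlation(counts, exp(age / 20), fdr = 0.2)
  expect_equal(res2$rho, res$rho, tolerance = 1e-12)
})
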
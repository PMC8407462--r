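#' Hypergeometric prevalence screen across demographic groups
#'
#' For each ASV and each demographic group, models the `k` carriers
#' among the group's `n` samples as draws from a cohort of `N` samples
#' with `K` carriers. `p_enriched = P(X >= k)` and
#' `p_depleted = P(X <= k)` under `Hypergeometric(N, K, n)`; the
#' reported two-sided p doubles the smaller tail (capped at 1) and the
#' direction marks which tail it was. BH correction runs across all
#' ASV x group tests.
#'
#' @param presence Logical matrix (samples x ASVs) or a single logical
#'   vector.
#' @param groups Factor/character vector of group labels per sample.
#' @param alpha FDR level.
#' @return Data frame with one row per ASV x group: `N, K, n, k`,
#'   `p_enriched`, `p_depleted`, `p` (two-sided), `q`, `direction`
#'   (`"+"` enriched / `"-"` depleted), `significant`.
#' @export
prevalence_enrichment <- function(presence, groups, alpha = 0.1) {
  if (is.vector(presence)) presence <- matrix(presence, ncol = 1,
                                              dimnames = list(NULL, "taxon"))
  stopifnot(nrow(presence) == length(groups))
  if (is.factor(groups) && any(table(groups) == 0)) stop("empty group")
  groups <- as.character(groups)
  N <- nrow(presence)
  K <- colSums(presence)
  out <- list()
  for (gr in unique(groups)) {
    sel <- groups == gr
    n <- sum(sel)
    k <- colSums(presence[sel, , drop = FALSE])
    p_enr <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_dep <- stats::phyper(k, K, N - K, n)
    out[[gr]] <- data.frame(
      asv_id = colnames(presence), group = gr, N = N, K = K, n = n, k = k,
      p_enriched = p_enr, p_depleted = p_dep,
      p = pmin(1, 2 * pmin(p_enr, p_dep)),
      direction = ifelse(p_enr <= p_dep, "+", "-"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  adj <- bh_fdr(res$p, alpha)
  res$q <- adj$q
  res$significant <- adj$reject
  res
}

#' Winsorise a numeric vector by the 1.5 IQR rule
#'
#' Quartiles use linear interpolation (quantile type 7). Values below
#' `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR` are replaced by those cutoffs;
#' everything else is untouched, so the transform is idempotent.
#'
#' @param values Numeric vector with at least 4 values.
#' @return Winsorised vector.
#' @export
winsorize_iqr <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric")
  ok <- !is.na(values)
  if (sum(ok) < 4) stop("need at least 4 non-missing values")
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  pmin(pmax(values, q[1] - 1.5 * iqr), q[2] + 1.5 * iqr)
}

#' Log-transform relative abundances with a half-minimum pseudocount
#'
#' @param rel Relative-abundance vector of one ASV.
#' @return `log(rel + pc)` with `pc` equal to half the smallest nonzero
#'   value; `NULL` when the ASV is never observed.
#' @export
log_abundance <- function(rel) {
  nz <- rel[rel > 0]
  if (!length(nz)) return(NULL)
  log(rel + min(nz) / 2)
}

#' Association of one ASV's abundance with one host factor
#'
#' Fits the linear model `factor ~ log-abundance` and reports the F
#' statistic of the abundance term (equal to the squared t of its slope
#' in the single-predictor model). When the abundance is more strongly
#' associated with age than with the factor (smaller univariate
#' p-value), the model is refit as `factor ~ log-abundance + age` and
#' the abundance term is tested by partial F.
#'
#' @param abundance Relative-abundance vector of the ASV.
#' @param factor_values Host-factor values (winsorise first, see
#'   [winsorize_iqr()]).
#' @param age Age vector for the conditioning step; `NULL` disables it.
#' @return List with `beta`, `F`, `p.value`, `age_adjusted`, `n_used`,
#'   or `NULL` when the ASV or the factor has zero variance or fewer
#'   than 10 usable samples.
#' @export
associate <- function(abundance, factor_values, age = NULL) {
  ok <- !is.na(abundance) & !is.na(factor_values) &
    (if (is.null(age)) TRUE else !is.na(age))
  x <- log_abundance(abundance[ok])
  y <- factor_values[ok]
  if (is.null(x) || sum(ok) < 10) return(NULL)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  fit1 <- stats::lm(y ~ x)
  s1 <- summary(fit1)$coefficients
  p_factor <- s1["x", "Pr(>|t|)"]
  age_adjusted <- FALSE
  beta <- s1["x", "Estimate"]
  Fstat <- s1["x", "t value"]^2
  p <- p_factor
  if (!is.null(age) && stats::sd(age[ok]) > 0) {
    a <- age[ok]
    s_age <- summary(stats::lm(a ~ x))$coefficients
    if (s_age["x", "Pr(>|t|)"] < p_factor) {
      fit2 <- stats::lm(y ~ x + a)
      s2 <- summary(fit2)$coefficients
      beta <- s2["x", "Estimate"]
      Fstat <- s2["x", "t value"]^2  # partial F of one term = t^2
      p <- s2["x", "Pr(>|t|)"]
      age_adjusted <- TRUE
    }
  }
  list(beta = unname(beta), F = unname(Fstat), p.value = unname(p),
       age_adjusted = age_adjusted, n_used = sum(ok))
}

#' Associate every ASV with every host factor
#'
#' Runs [associate()] for each ASV x factor pair (factors winsorised
#' first) and applies BH correction across all tested pairs.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param metadata Metadata data frame aligned to the samples.
#' @param factors Character vector of numeric metadata columns to test.
#' @param age_var Name of the age column used for conditioning (`NULL`
#'   to disable); never tested as a factor itself.
#' @param fdr FDR level.
#' @param min_prevalence Skip ASVs observed in fewer than this
#'   proportion of samples.
#' @return Data frame: `asv_id`, `factor`, `beta`, `F`, `p`, `q`,
#'   `age_adjusted`, `n_used`, `significant`.
#' @export
associate_all <- function(counts, metadata, factors, age_var = "age",
                          fdr = 0.2, min_prevalence = 0.10) {
  stopifnot(nrow(metadata) == nrow(counts))
  rel <- counts / rowSums(counts)
  keep <- colMeans(counts > 0) >= min_prevalence
  age <- if (is.null(age_var)) NULL else metadata[[age_var]]
  fw <- lapply(factors, function(f) winsorize_iqr(metadata[[f]]))
  names(fw) <- factors
  rows <- list()
  for (a in colnames(rel)[keep]) {
    for (f in factors) {
      r <- associate(rel[, a], fw[[f]], age)
      if (is.null(r)) next
      rows[[length(rows) + 1]] <- data.frame(
        asv_id = a, factor = f, beta = r$beta, F = r$F, p = r$p.value,
        age_adjusted = r$age_adjusted, n_used = r$n_used,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(asv_id = character(), factor = character(),
                      beta = numeric(), F = numeric(), p = numeric(),
                      q = numeric(), age_adjusted = logical(),
                      n_used = integer(), significant = logical()))
  adj <- bh_fdr(res$p, fdr)
  res$q <- adj$q
  res$significant <- adj$reject
  rownames(res) <- NULL
  res
}

#' Diet-pattern principal-component analysis
#'
#' Standardises the food-group intake columns (zero mean, unit
#' variance; constant columns are dropped with a warning) and runs PCA.
#' Each axis is oriented so that its largest-magnitude loading is
#' positive.
#'
#' @param food_groups Numeric matrix or data frame (samples x food
#'   groups).
#' @return List with `loadings` (food groups x axes), `scores`
#'   (samples x axes), `variance_explained` (sums to 1 over all axes).
#' @export
diet_pca <- function(food_groups) {
  X <- as.matrix(food_groups)
  stopifnot(is.numeric(X))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant food group(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  list(loadings = rot, scores = scores,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Spearman correlation of age with alpha diversity, per sex
#'
#' @param richness Per-sample observed ASV richness.
#' @param age Age vector.
#' @param sex Sex labels; each stratum needs at least 10 samples.
#' @return Data frame with one row per stratum (plus `"all"`): `rho`,
#'   `p`, `n`.
#' @export
age_diversity_correlation <- function(richness, age, sex) {
  strata <- c(as.list(split(seq_along(age), sex)), list(all = seq_along(age)))
  out <- lapply(names(strata), function(s) {
    idx <- strata[[s]]
    if (length(idx) < 10) stop("fewer than 10 samples in stratum ", s)
    if (stats::sd(age[idx]) == 0 || stats::sd(richness[idx]) == 0)
      stop("constant input in stratum ", s)
    sp <- spearman_rho_p(age[idx], richness[idx])
    data.frame(stratum = s, rho = sp$rho, p = sp$p.value, n = length(idx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman correlation of each ASV's abundance with age
#'
#' Log abundance (half-minimum pseudocount, as in [associate()]) against
#' age, BH-corrected across ASVs.
#'
#' @param counts Count matrix (samples x ASVs).
#' @param age Age vector.
#' @param fdr FDR level.
#' @param min_prevalence Skip ASVs below this prevalence.
#' @return Data frame: `asv_id`, `rho`, `p`, `q`, `significant`.
#' @export
age_abundance_correlation <- function(counts, age, fdr = 0.2,
                                      min_prevalence = 0.10) {
  rel <- counts / rowSums(counts)
  keep <- colnames(rel)[colMeans(counts > 0) >= min_prevalence]
  rows <- lapply(keep, function(a) {
    x <- log_abundance(rel[, a])
    if (is.null(x)) return(NULL)
    sp <- spearman_rho_p(x, age)
    if (is.na(sp$rho)) return(NULL)
    data.frame(asv_id = a, rho = sp$rho, p = sp$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(asv_id = character(), rho = numeric(), p = numeric(),
                      q = numeric(), significant = logical()))
  adj <- bh_fdr(res$p, fdr)
  res$q <- adj$q
  res$significant <- adj$reject
  rownames(res) <- NULL
  res
}
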
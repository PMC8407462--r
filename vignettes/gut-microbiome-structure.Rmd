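---
title: "Methods: enterotypes, cooccurrence clusters and host-factor associations in cohort-scale 16S data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enterotypes, cooccurrence clusters and host-factor associations in cohort-scale 16S data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gutstruct implements the downstream half of a cohort-scale 16S rRNA
gut-microbiome study: everything that happens after an ASV (amplicon
sequence variant) count table, a taxonomy, a rooted phylogeny and host
metadata exist. Raw-read processing (primer trimming, denoising,
taxonomic classification) is out of scope. This vignette documents the
models and the numerical choices, and what the synthetic-cohort tests
do and do not establish about real data.

## The data model

The root object is an integer count matrix, samples in rows and ASVs in
columns, paired with a taxonomy table (kingdom through species, ranks
possibly unassigned), a rooted tree whose tips are the ASVs, and a
per-sample metadata table. Samples are retained when they carry more
than 10,000 reads, the standard quality gate for this kind of survey.
ASVs are displayed as "lowest assigned taxon + rank of total read
count" (`assign_display_names()`): the most abundant ASV classified as
*Faecalibacterium prausnitzii* becomes "Faecalibacterium prausnitzii
ASV 1". Ties in total count break by lexicographic ASV id so the naming
is reproducible.

Prevalence of a taxon is the fraction of samples with nonzero reads;
relative abundance is reads over the sample total, aggregated by
summing counts before dividing. Alpha diversity is observed ASV
richness only — the analysis this package supports plots "number of
ASVs" and nothing else, so Shannon and Faith's PD are deliberately
absent.

## Weighted UniFrac and ordination

`weighted_unifrac()` computes the unnormalised weighted UniFrac
distance: the sum over branches of branch length times the absolute
difference in the fraction of each community's abundance descending
through that branch. The unnormalised form matches the default of the
QIIME2 diversity stack. `unifrac_matrix()` assembles, in one postorder
pass, a samples-by-branches mass matrix; scaling its columns by branch
length turns every pairwise distance into a Manhattan distance between
rows, so the full 890-sample matrix is one `dist()` call. Tests verify
the fast path against a naive per-branch oracle to 1e-12 and check the
metric axioms on random instances.

`pcoa_ordination()` is classical scaling: double-centre `-D^2/2`,
eigendecompose, scale eigenvectors by the square root of their
eigenvalues. Distance matrices that are not exactly Euclidean produce
negative eigenvalues; these are reported but their axes are dropped,
with no Cailliez correction — the simplest defensible choice, and the
count of negative eigenvalues is part of the return value so a user can
see when it matters. Rarefaction is not performed before UniFrac; the
package computes on full relative abundances and states so.

## Enterotypes

Enterotypes are fit by embedding the weighted UniFrac matrix in its
leading 10 principal coordinates (configurable) and fitting a
two-component Gaussian mixture; each cluster is then named by the genus
with the highest mean relative abundance among its samples. Two
numerical choices matter here:

* **Covariance model.** The mixture defaults to a pooled full
  covariance shared by both components (`model = "EEE"` in mclust's
  vocabulary), initialised from k-means with ten restarts. With
  unconstrained per-component covariances in a 10-dimensional
  embedding, the likelihood admits degenerate "spike" optima that carve
  off dense subregions rather than the two community types; we observed
  recovery of planted labels collapse on some simulated cohorts for
  exactly this reason. The pooled model removes those optima while
  remaining a genuine Gaussian mixture; a degenerate fit, should one
  still occur, triggers a logged spherical refit.
* **K.** Fixed at 2 by default. A BIC scan over K = 2..6 is computed
  and returned for inspection but never used for labelling.

Label transfer to an external cohort is nearest-neighbour: each foreign
sample takes the enterotype of the reference sample at the shortest
UniFrac distance, ties to the lowest reference index. This requires
the two cohorts to share an ASV space (a joint denoising run in
practice; the synthetic generator guarantees it by construction).

Three cross-cohort comparisons are provided: a Yates-corrected 2x2
chi-squared test on enterotype counts (`compare_et_proportions()`,
which reproduces the published worked examples to their printed
precision); a one-way PERMANOVA on the distance matrix with the
pseudo-F computed from the within/between sum-of-squares decomposition
and a `(1 + #{F* >= F}) / (1 + n_perm)` permutation p-value (never
exactly zero), with exhaustive enumeration available at small n so the
permutation machinery can be tested against brute force; and a
Mann-Whitney comparison of average within-enterotype distances
(`avg_distance_test()`), foreign-to-reference versus
reference-to-reference with self excluded. Fully tied averages return
p = 1 by convention.

## The cooccurrence network and microbial clusters

Only ASVs present in at least 10% of samples enter the network. Every
pair is tested twice:

* **Cooccurrence**: a two-sided Fisher exact test on the 2x2
  presence/absence table, implemented by direct hypergeometric
  enumeration (and verified against `fisher.test` and an independent
  oracle). The direction is positive when joint presence exceeds its
  independence expectation — more robust than an odds ratio when a cell
  is zero. ASVs present or absent everywhere are flagged and given
  p = 1 rather than excluded silently.
* **Quantitative association**: Spearman correlation of
  log-transformed abundances over the samples where *both* ASVs are
  present, with mid-rank ties and the t approximation for the p-value
  (the same approximation the reference Python stack uses). Pairs with
  fewer than 10 joint observations are excluded — the threshold is a
  package choice that prevents spurious perfect correlations on tiny
  overlaps. Rank statistics make the log base irrelevant; natural log
  is used.

Benjamini-Hochberg correction runs separately within each family; an
edge requires both a positively-directed Fisher q below 1e-6 and a
positive rho with q below 1e-3. The conjunctive rule is the default
reading of the published criterion; a union rule is available via
`rule = "union"`. Counts passing each criterion separately are always
reported.

Clusters are extracted by a deterministic version of a procedure that
was originally partly manual: (1) enumerate 3-cliques; (2) merge
cliques sharing a node (connected components of the subgraph of edges
that lie in at least one triangle); (3) split each group into
phylum-consistent subgroups (components of the same-phylum induced
subgraphs); (4) attach remaining network nodes adjacent to a subgroup
member carrying the same lowest-taxon label, iterated to a fixed
point, first-qualifying-subgroup order; (5) name each cluster after its
highest-total-count member, suffixing C1, C2, ... when names collide;
drop clusters below 3 members. Steps 3-4 are an automation of a
"manually disjointed by phylum, joined same-taxon neighbours"
description and are flagged as an interpretation.

Negative quantitative associations (rho < 0, BH within the negative
family at 1e-3) are screened by the same machinery and reported as a
separate edge list, never as clusters.

## Host-factor analyses

**Prevalence screen.** For ASV presence within a demographic group,
`prevalence_enrichment()` uses the hypergeometric model: k carriers in
a group of n drawn from N samples with K carriers overall. Both tails
are computed; the reported two-sided p doubles the smaller tail (capped
at 1) since the original analysis reports both enrichment ("+") and
depletion ("-") without stating sidedness. BH runs across all
ASV-by-group tests at FDR 0.1. Age groups default to decades — the
original binning is not stated numerically, and the choice is labelled
in output.

**Association model.** Host factors are winsorised by the 1.5 IQR rule
with type-7 (linear interpolation) quartiles — the quartile convention
is unstated upstream, so it is fixed and documented here. ASV
abundance enters as log relative abundance with a per-ASV pseudocount
of half the smallest nonzero value (the zero policy is likewise a
package choice; a nonzero-only mode matching the network transform is
a config option). The fitted model predicts the host factor from log
abundance; the F statistic of the abundance term equals the squared t
of its slope in the single-predictor fit, which the tests assert
numerically. When the abundance is more strongly associated with age
than with the factor — operationalised as a smaller univariate p-value,
the comparator being unstated upstream — age joins the model and the
abundance term is tested by partial F. BH runs across all
ASV-by-factor pairs at FDR 0.2.

**Diet PCA.** The 17 food-group intakes are standardised (they mix
scales) and decomposed by PCA; each axis is oriented so its
largest-magnitude loading is positive, making signs reproducible.
Variance explained sums to one over all axes.

**Age trends.** Spearman correlations of age with observed richness
(per sex stratum) and with per-ASV log abundance (BH at FDR 0.2), plus
a 10-year moving-average smoother for presentation.

## The synthetic cohort generator

The generator (`cohort_spec()` / `generate_cohort()`) exists so that
every stage above is testable without sequencing data. It emulates, at
the level of statistical structure:

* a two-enterotype mixture, 60/40 by default, with genus profiles
  anchored at the published dominant-genus abundances (Bacteroides
  enterotype: Bacteroides 35.3%, Faecalibacterium 14.2%, Prevotella 2%;
  Prevotella enterotype: Prevotella 37.1%, Faecalibacterium 11.7%,
  Bacteroides 10.4%), minor-genus mass filled with fixed weights;
* per-sample genus composition as a Dirichlet perturbation of the
  enterotype profile. The concentration defaults to 100, chosen so that
  the dominant genus contradicts the planted enterotype in only ~1-2%
  of samples — i.e. so dominant-genus labelling is effectively
  deterministic, which is the design intent of anchoring the profiles;
  at much lower concentrations no clustering method could match the
  planted labels because the labels themselves become ambiguous;
* planted cooccurrence blocks, each realised as a designated minor
  genus whose ASVs share a latent Gaussian factor driving both
  structural presence (probit, marginal prevalence 0.55) and
  log abundance (equal shared and private log-normal sds of 0.8, hence
  within-block rank correlations near 0.5). Making blocks whole genera
  keeps them phylum- and taxon-consistent — mirroring the largely
  same-taxon composition of the real clusters — and keeps background
  same-genus compositional correlation from blurring block boundaries;
* the Bacteroides-Prevotella anticorrelation, which emerges from the
  mixture rather than being inserted;
* age ~ Normal(55.6, 15.0) truncated to [19, 90], 77.5% female,
  log-normal library sizes with mean 30,000 reads floored just above
  the 10,000-read gate;
* 17 food groups driven by two latent diet axes — the first
  grain-dominated, the second a Westernised-vs-traditional contrast
  coupled to age at rank correlation -0.51;
* planted host-factor effects: the named factor gains beta times the
  z-scored log relative abundance of the named ASV, plus Normal(0, 1)
  noise. Beta is therefore in factor units per standard deviation of
  log abundance. An optional stratum column restricts an effect to one
  sex so stratified analyses can be exercised. With planted effects of
  0.5 this puts host-factor variances near 1, smaller than a realistic
  BMI spread; the calibration replicates are conditions under which the
  planted effect is detectable, not a claim about power on real
  cohorts.

Per-ASV dispersion is not reported by any cohort survey at this level,
so the generator's dispersion parameters are free; they are recorded in
the ground-truth object of every cohort it draws.

The tree generator coalesces same-genus ASVs (short branches,
0.01-0.10) before joining genera (long branches, 0.10-0.50), so UniFrac
geometry reflects taxonomy. All randomness flows through one seed;
identical specs reproduce byte-identical cohorts.

### What the calibrations mean — problem sizes and truth sets

The packaged calibration runs use: an 800-890-sample cohort with 300
ASVs for enterotype recovery and block recovery (adjusted Rand index,
nearest-neighbour transfer accuracy, per-block best-match Jaccard); 200
replicate cohorts of 120 samples and 60 ASVs for association power and
empirical FDR; 1,000 random label draws on a 40-sample cohort for
PERMANOVA size; 200 effect-free replicates for the association test's
size.

Two choices in the association calibration deserve a note. The
replicates are drawn single-enterotype: in a two-enterotype mixture,
any factor carrying a planted effect inherits a weak but *real*
marginal correlation with the enterotype axis, and through it with
every taxon tied to that axis, so "false positive" would be ill-defined.
Second, block-mates of the planted ASV count as true discoveries: they
share its latent factor, so their marginal association with the factor
is genuine. The empirical FDR is the mean over replicates of the false
fraction of calls — the quantity BH controls.

Passing these calibrations shows the pipeline recovers the structure
the generator plants, at the stated sizes, under Dirichlet-multinomial
noise. Real 16S data have features the generator does not emulate —
stronger zero inflation, per-ASV overdispersion beyond log-normal,
batch effects, correlated measurement error in food-frequency
questionnaires — so recovery rates here are upper bounds, not
predictions, for field performance.

## Degenerate inputs and tie-breaks, collected

* Read filter: strictly more than `min_reads` reads keeps a sample.
* Prevalence filter: at least `min_prev` (inclusive) keeps an ASV.
* Display-name ties: lexicographic ASV id.
* Nearest-neighbour ties: lowest reference index.
* Constant presence/absence vectors: flagged, Fisher p = 1.
* Constant ranks on a Spearman overlap: pair excluded, logged.
* All-tied average-distance comparison: p = 1.
* All-zero distance matrix: PERMANOVA refuses (F undefined); PCoA
  returns an all-zero embedding.
* Permutation p-values never return 0 by construction.
* Winsorisation is idempotent; an all-equal vector passes through.
* Zero margins in the 2x2 enterotype table: flagged, p undefined.

## Limitations

Compositionality is handled by rank statistics and presence tests, not
by log-ratio transforms; SparCC/SPIEC-EASI-style corrected networks are
out of scope, and a strong positive effect on one taxon necessarily
shadows others negatively in relative abundance (visible in the
age-abundance screen's tests). Cross-cohort transfer assumes a shared
ASV space. The Gaussian-mixture enterotype model with K = 2 is a
modelling commitment, not an inference about the true number of
community types; the BIC scan is reported for transparency.
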
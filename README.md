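# gutstruct

Downstream analysis of cohort-scale 16S rRNA gut-microbiome surveys,
built for the question a healthy-population study asks: what does the
community structure of a large cohort look like, how does it compare
with other populations, which microbes travel together, and which host
factors move them?

Starting from an ASV (amplicon sequence variant) count table, a
taxonomy, a rooted phylogeny and host metadata, the package provides:

* **Community metrics** — prevalence, relative abundance, observed
  richness, unnormalised weighted UniFrac
  (`d(A,B) = Σ_b ℓ_b · |P_A(b) − P_B(b)|` over branches `b`, with
  `P_X(b)` the fraction of community X's abundance descending through
  `b`), and principal-coordinate analysis.
* **Enterotypes** — a K = 2 Gaussian mixture on the leading PCoA axes
  of the UniFrac matrix, clusters labelled by their dominant genus;
  nearest-neighbour enterotype transfer to external cohorts; Yates-
  corrected chi-squared comparison of enterotype ratios; one-way
  PERMANOVA (pseudo-F from the distance sum-of-squares decomposition,
  permutation p); Mann-Whitney comparison of average within-enterotype
  distances.
* **Cooccurrence network and microbial clusters** — for every ASV pair
  above 10% prevalence, a two-sided Fisher exact test on joint
  presence and a Spearman test on log abundances over jointly-present
  samples; edges need both criteria (BH FDR < 10⁻⁶ and < 10⁻³
  respectively, positive direction); clusters come from 3-cliques
  merged, split by phylum, extended to same-taxon neighbours and named
  after their most abundant member. Negative associations are screened
  separately.
* **Host-factor analyses** — hypergeometric prevalence
  enrichment/depletion by demographic group (BH FDR < 0.1); winsorised
  (1.5 IQR), age-conditioned linear association of host factors with
  log ASV abundance tested by partial F (BH FDR < 0.2); diet-pattern
  PCA on 17 standardised food groups; age-diversity and age-abundance
  Spearman trends.
* **A synthetic cohort generator** — a two-enterotype
  Dirichlet-multinomial community with planted cooccurrence blocks,
  planted host-factor effects and realistic demographics, plus the
  ground truth needed to score recovery. Every stage of the pipeline is
  tested against it.

## Worked example

```r
library(gutstruct)

co  <- generate_cohort(cohort_spec(n_samples = 250, seed = 7))
d   <- unifrac_matrix(co$tree, co$counts)
m   <- fit_enterotypes(d, co$counts, co$taxonomy, K = 2, seed = 8)
table(m$et_names)
#>
#> Bacteroides  Prevotella
#>         138         112

mclust::adjustedRandIndex(m$labels, co$ground_truth$et_labels)
#> [1] 0.9523838

res <- compare_et_proportions(c(536, 354), c(327, 85))
res$p.value
#> [1] 1.663062e-11
```

The cohort splits roughly 60/40 between a Bacteroides-dominated and a
Prevotella-dominated enterotype; the mixture recovers the planted
labels almost perfectly (adjusted Rand index 0.95 here). The last call
is the published worked example comparing a 536/354 reference cohort
with a 327/85 foreign cohort: Yates-corrected chi-squared p ≈ 1.7e-11,
i.e. the foreign population is far richer in the Bacteroides
enterotype.

The full analysis is organised as numbered drivers over the package:

```sh
Rscript analysis/01_simulate.R          # synthetic study cohort -> results/cohort/
Rscript analysis/02_diversity.R         # UniFrac, PCoA, richness
Rscript analysis/03_enterotypes.R       # mixture fit + ratio comparisons
Rscript analysis/04_network.R           # dual-criterion network + clusters
Rscript analysis/05_host_association.R  # prevalence screen, associations, diet PCA
```

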
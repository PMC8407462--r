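Package: gutstruct
Title: Gut Microbiome Community Structure, Enterotypes, and Host-Factor
    Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of 16S rRNA amplicon sequence variant
    (ASV) tables from large healthy cohorts: weighted UniFrac distances
    and principal-coordinate ordination, Gaussian-mixture enterotype
    detection and nearest-neighbour enterotype transfer across cohorts,
    dual-criterion (cooccurrence plus positive quantitative association)
    microbial network construction with clique-based cluster extraction,
    hypergeometric prevalence screening across demographic groups, and
    winsorised age-conditioned linear association of ASV abundance with
    host factors under Benjamini-Hochberg false-discovery-rate control.
    Includes a synthetic cohort generator that emulates a two-enterotype
    community with planted cooccurrence blocks and planted host-factor
    effects, so every stage can be exercised and calibrated without
    access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
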
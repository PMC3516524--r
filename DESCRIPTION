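Package: ancestryx
Title: Gene-Ancestry Interaction Testing for Multi-Cohort GWAS
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects susceptibility gene-ancestry interactions in
    genome-wide association studies that combine closely related
    populations. Individuals are clustered into ancestry groups from the
    leading principal components of the genotype matrix (EIGENSTRAT
    normalization, k-means with BIC selection of the number of clusters)
    and each marker is tested for heterogeneous association across
    clusters with a BIC-difference statistic (T). When a second, design-
    fixed grouping (the collection label) is available, the difference of
    the two T statistics (D) separates true ancestry interactions from
    collection artefacts. Significance thresholds for D are calibrated by
    retrospective simulation of null genotypes conditional on the observed
    phenotype. Also included: proxy-label replication tests, pooled
    meta-analytic fits, switch-rate power analysis for replication design,
    and a Balding-Nichols synthetic-GWAS generator with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    metafor,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
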
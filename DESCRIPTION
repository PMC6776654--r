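Package: gutdialogue
Title: Family-Aware Microbiome-Metabolome Association and Gut-Host
    Dialogue Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the interplay between the gut microbiome
    and host metabolism in twin cohorts. Implements a synthetic
    twin-cohort generator (zero-inflated compositional species and
    pathway tables, log-scale metabolite panels with planted effects,
    family covariance and run-day batches), the preprocessing transforms
    used for microbial relative abundances and metabolite intensities
    (arcsine square-root, iterative Grubbs outlier filtering, run-day
    median scaling, rank-based inverse-normal transform, PCA sample
    outlier detection), a variance-component mixed-model association
    screen with pedigree-expected kinship and Storey q-value false
    discovery control, presence/absence sharing statistics, parametric
    gene-set enrichment (PAGE) over metabolite super-pathways, metabolite
    to metabolic-pathway linking, and a gut-host "dialogue" detection
    stage based on missingness-matched correlation simulations and an
    empirically calibrated P-gain threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
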
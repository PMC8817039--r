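Package: phewasnet
Title: Phenome-Wide Association Scans with Post-PheWAS Network, Causal and
    Heritability Analyses
Version: 0.1.0
Authors@R:
    person("GENIE", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for phenome-wide association studies (PheWAS) on
    deeply phenotyped cohorts and for the systematic analyses that follow
    them: cross-phenotype association extraction, bipartite phenotype and
    gene networks, split-sample network-wide Mendelian randomization (IVW,
    MR-Egger, weighted median), LD-aware multiple-testing calibration via
    greedy pruning, simplified single-component LD-score-regression
    heritability, fixed-effect inverse-variance meta-analysis across
    cohorts, and concordance of genotype-driven versus EHR-driven
    phenotype pairs.  A synthetic cohort generator with known pleiotropic
    and causal architecture provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils,
    methods,
    IRanges,
    S4Vectors,
    GenomicRanges,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
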
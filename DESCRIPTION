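Package: lipmed
Title: Genetic Association and Causal Mediation for Lipid-Mediated Disease Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for SNP-lipid-disease relationships:
    genotype quality control (allele frequencies, exact Hardy-Weinberg
    test, linkage-disequilibrium r-squared and tag-set selection),
    longitudinal lipid association models with cluster-robust sandwich
    variance, Cox proportional-hazards disease models on the age axis,
    conditional-attenuation summaries, natural direct and indirect effect
    estimation for time-to-event outcomes with continuous mediators
    (rare-outcome product method and a weighted natural-effect Cox model)
    with bootstrap inference, fixed-effect inverse-variance meta-analysis
    across cohorts, and a synthetic multi-cohort generator emulating the
    assumed data structure so every stage is testable without
    access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    MASS,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    metafor,
    igraph,
    vcfR,
    yaml
Config/testthat/edition: 3
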
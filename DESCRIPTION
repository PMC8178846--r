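Package: dormsig
Title: Tumor-Dormancy Gene Signatures, Survival Meta-Analysis, and
    Limiting-Dilution Frequency Estimation
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives cross-model tumor-dormancy gene expression signatures
    from grouped log2 expression matrices using a Bayesian-regularized
    (Cyber-T style) t-test with Benjamini-Hochberg FDR control, scores
    samples and patient cohorts with signed gene lists via weighted
    z-score averaging, relates median-dichotomized signature scores to
    survival with per-cohort Cox proportional-hazards fits combined by
    inverse-variance meta-analysis (Cochran's Q heterogeneity test with
    DerSimonian-Laird random effects), tests gene-set overlap enrichment,
    and estimates tumor-initiating cell frequency from limiting-dilution
    assays under the single-hit Poisson model. Ships a synthetic-data
    generator emulating the statistical structure of two-model mouse
    residual-lesion experiments and multi-cohort patient survival data,
    plus an end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
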
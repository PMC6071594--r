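Package: BreedGS
Title: Genomic Selection Analysis for Multi-Year Wheat Yield-Trial Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running genomic selection in a line-breeding program:
    spatially adjusted per-location BLUPs for grain yield from augmented or
    alpha-lattice trials (REML with iid or separable AR1xAR1 residuals and
    AIC-based model selection), broad-sense heritability within and across
    locations, SNP marker quality control and genomic relationship matrix
    construction, GBLUP fitted by Gibbs sampling or eigendecomposition REML,
    year-structured cross-validation schemes (NA10-NA100 masking and
    skip-year forward prediction) with predictive-ability summaries,
    train/test kinship diagnostics (maximum realized kinship, PCA), and
    genomic-versus-phenotypic selection tracking of advanced lines. A
    synthetic breeding-program simulator (multi-year cohorts of near-inbred
    lines, additive QTL with genotype-by-environment deviations, augmented
    layouts with replicated checks, AR1xAR1 spatial field trends) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
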
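# BreedGS

Genomic selection analysis for multi-year yield-trial programs in
self-pollinated crops, built around the workflow of a public winter-wheat
breeding program: hundreds of near-inbred lines enter a preliminary yield
trial (PYT) each year, are grown in augmented designs with replicated
checks at many locations, and ~20% are advanced to replicated trials the
following year. BreedGS is for breeders and quantitative geneticists who
want to run — or stress-test on simulated data — the full chain from plot
yields to genomic selection decisions.

The chain, each step an exported function:

1. **Spatial trial adjustment** — per location-year, REML mixed models
   `y = checks (fixed) + line + block/row/col (random) [+ AR1xAR1 spatial
   field] + e`, compared by REML AIC; per-line BLUPs averaged across
   locations into one value per line-year.
2. **Heritability** — within a location, `H = σ²G / (σ²G + σ²R / r)`;
   across the `L` locations of a year, from `blup = μ + location(fixed) +
   line(random) + e`, `H = σ²G / (σ²G + σ²R / L)`.
3. **Marker QC and the GRM** — missingness > 80%, MAF < 0.05, allelic
   R² < 0.5 filters; dosage coding 2/0/1; `G = XX'/p` on the
   column-centered, column-scaled dosage matrix.
4. **GBLUP** — `y = μ + g + e`, `g ~ N(0, Gσ²g)`, fitted by a Gibbs
   sampler (scaled-inv-χ² priors, 12,000 iterations / 2,000 burn-in) or
   by a deterministic eigendecomposition REML solver; masked lines are
   predicted through the genomic covariances.
5. **Cross-validation** — the NA10–NA100 schemes: mask 10–100% of one
   year's cohort, train on the rest plus all other cohorts, 10 random
   repeats; predictive ability = Pearson correlation of test-set GEBVs
   with test-set BLUPs. Skip-year schemes for forward prediction.
6. **Kinship & structure** — per-test-line maximum realized kinship
   coefficient (MRKC) against the training set; PCA of the
   centered-scaled genotype matrix.
7. **Selection tracking** — genomic vs phenotypic selection correlations
   for advanced lines, and BLUP/GEBV quadrant tracking by years retained.

A synthetic breeding-program generator (multi-year cohorts of near-inbred
lines with family structure, additive QTL, G×E deviations, augmented
layouts, exact AR1×AR1 field trends) makes every stage testable without
external data. See `vignettes/genomic-selection-methods.Rmd` for the
models, defaults and limitations.

## Worked example

```r
library(BreedGS)

cfg <- simConfig(n_founders = 60, n_markers = 500, n_years = 4,
                 lines_per_year = 120, n_qtl = 80, seed = 2025)
sim <- simulateCohorts(cfg)
sim$panel
#> GenotypePanel: 480 lines x 500 markers
#>   missing calls: 0.00%; map: yes; allelic R2: no

## adjust one trial, comparing the model catalogue by REML AIC
trial <- simulateTrial(sim, cfg, 2012, 1)
selectModel(trial)$table[, c("model", "aic", "converged")]
#>            model     aic converged
#> 1      iid_block 1032.87      TRUE
#> 2     iid_rowcol 1034.05      TRUE
#> 3        ar1xar1 1032.50      TRUE
#> 4  ar1xar1_block 1034.50      TRUE
#> 5 ar1xar1_rowcol 1036.50      TRUE

fit <- fitLocationModel(trial, modelSpec("iid_block", "block", "iid"))
h2WithinLocation(fit, r = 1)
#> H = 0.787 (within_location, divisor 1); sigma_G2 = 94.62, sigma_R2 = 25.65
```

The within-location heritability (0.787 here) is the fraction of line
variance in total plot variance of this unreplicated augmented trial; the
genetic and residual variances are separated by the replicated checks.
Fitting the across-location model (`h2AcrossLocations()`) on the
per-location BLUPs of the same year's four locations gives `H = 0.803`,
the usual gain from treating locations as replicates.

```r
## GRM and cross-validated genomic prediction
panel <- filterMafQuality(sim$panel, maf_min = 0.05, r2_min = NULL)
grm <- computeGrm(encodeNumeric(panel))
grm
#> Grm: 480 lines, 474 markers used
#>   mean diagonal: 0.9979

y <- simulateLineMeans(sim, h2 = 0.5, seed = 2025)  # or BLUPs from step 1
schemes <- c(buildNaSchemes(sim$cohorts, 2012, c(0.1, 0.5), n_repeats = 5, seed = 1),
             buildNaSchemes(sim$cohorts, 2012, 1, seed = 1))
summarizePa(runCv(y, grm, schemes, method = "reml"))
#>   scenario target_year mean_pa n_repeats
#> 1     NA10        2012   0.484         5
#> 2    NA100        2012   0.538         1
#> 3     NA50        2012   0.576         5

mrkc(grm, names(sim$cohorts)[sim$cohorts == 2012],
     names(sim$cohorts)[sim$cohorts != 2012])
#> MRKC over 120 test vs 360 training lines: mean 0.506 (range 0.285-0.816)
```

`mean_pa` is the average, over random repeats, of the correlation between
predicted and observed (adjusted) phenotypes of the masked lines — the
quantity a breeder reads as "how well would I have ranked the lines I did
not phenotype". The mean diagonal of the GRM equals `(n-1)/n` by
construction, a quick integrity check after any filtering. The MRKC
summary says how closely each masked line is related to its best relative
in the training set, the main driver of its prediction accuracy.

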
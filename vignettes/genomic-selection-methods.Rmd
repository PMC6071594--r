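---
title: "Methods: spatially adjusted trial analysis and genomic prediction in BreedGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially adjusted trial analysis and genomic prediction in BreedGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(BreedGS)
```

BreedGS implements the analysis chain a line-breeding program runs between
harvesting a multi-location yield trial and making genomic selections:
per-location mixed-model adjustment of plot yields, heritability
estimation, marker quality control, genomic relationship matrix (GRM)
construction, GBLUP prediction, year-structured cross-validation, and
diagnostics that compare genomic and phenotypic selection. This vignette
records the models, the tunable parameters and their defaults, the
numerical choices, and the known limitations — in particular what the
bundled synthetic generator does and does not emulate.

## Per-location trial adjustment

Each location-year is analyzed separately. The observation model is

$$y = X\tau + Z_g g + \textstyle\sum_k Z_k u_k + s + e$$

where the fixed part $X\tau$ is always the intercept plus one indicator
per replicated check cultivar, $g$ are iid random effects of the
experimental lines, the optional $u_k$ are iid random design terms
(incomplete block, field row, field column; a replicate term and
block-within-replicate nesting are added automatically for replicated
lattice trials), and $e \sim N(0, \sigma^2_R I)$ is the iid residual. For
the spatial members of the model catalogue, $s$ is a random field whose
correlation is separable first-order autoregressive over field rows and
columns, $\mathrm{AR1}(\rho_r)\otimes\mathrm{AR1}(\rho_c)$, with its own
variance $\sigma^2_{sp}$; the iid residual is retained as a nugget. We
chose the "spatial component + nugget" formulation (rather than replacing
the residual by the AR1xAR1 correlation) because plot data always carry
measurement noise on top of a smooth trend; without the nugget the
autocorrelation estimates absorb the noise and are biased downward.

Estimation is by profiled REML: the iid residual variance carries the
profiled scale and the optimizer works on log variance ratios plus
$\tanh^{-1}$-transformed correlations (Nelder-Mead; Brent when only one
ratio is free). Spatial fits start from a coarse $3\times3$ grid over
$(\rho_r, \rho_c) \in \{0.2, 0.5, 0.8\}^2$ with short inner
optimizations, then refine jointly. Convergence tolerance is $10^{-6}$ on
the log-likelihood with an iteration cap of 200 (Nelder-Mead is allowed
`5 * maxIter` function evaluations); non-convergence is an error unless
`strict = FALSE`. Variance ratios are bounded in $[e^{-20}, 10^8]$;
ratios below $10^{-6}$ flag a boundary solution. Trials with zero yield
variance return a flagged fit with $\sigma^2_G = 0$ and zero BLUPs. Plot
coordinates are 1-based grid indices and plots need not fill the
rectangle: the likelihood uses the observed subset of the lattice.

Model selection compares the catalogue
`{iid+block, iid+row+col, ar1xar1, ar1xar1+block, ar1xar1+row+col}` by
REML AIC. All members share the identical fixed part, which is the
standard condition for comparing REML likelihoods; the AIC penalty counts
variance and correlation parameters only. Ties are broken toward fewer
variance parameters. Residual skewness and a linear column-trend
t-statistic are attached per model as diagnostics.

Per-line BLUPs from the selected model at each location are averaged,
unweighted, into one value per line-year (`combineLocations()`); lines
missing everywhere are dropped, and the number of contributing locations
is reported.

## Heritability

Within a location, broad-sense heritability is the plug-in
$H = \sigma^2_G / (\sigma^2_G + \sigma^2_R / r)$ with $r$ the number of
replicates ($r = 1$ for unreplicated augmented trials, where the
replicated checks separate the genetic and residual variances). Across
locations within a year, the model $\mathrm{blup} = \mu + L + g + e$ is
fitted by REML (through lme4) on the per-location BLUP table with
location fixed — locations are preselected by the program, not sampled —
and $H = \sigma^2_G / (\sigma^2_G + \sigma^2_R / L)$ with $L$ the number
of locations. Negative component estimates are clipped at zero and
flagged. `h2Accumulation()` recomputes $H$ on the first $k$ locations of
a stated ordering, $k = 2, \dots, L$.

## Marker quality control and the GRM

Genotype calls use the half-dosage coding of the deposited-panel dialect
(1 homozygous major, 0 homozygous minor, 0.5 heterozygous). Filters
follow the study's thresholds and strictness: markers missing in more
than 80% of lines are removed (exactly 80% is kept); markers with minor
allele frequency below 0.05 or imputation allelic $R^2$ below 0.5 are
removed (values at the threshold are kept). MAF counts heterozygotes as
half an allele and is computed from integer allele counts so that
threshold comparisons are exact. Imputation itself is out of scope: the
allelic $R^2$ score is consumed as given (and simulated uniformly when
testing the filter).

Encoding doubles the calls to the 2/0/1 dosage scale. The GRM is
$G = X X' / p$ on the column-centered, column-scaled dosage matrix of $p$
markers. The standard deviation uses the $n-1$ denominator — the original
scaling is not stated to that precision, and $n-1$ yields the exact
identity $\mathrm{mean}(\mathrm{diag}(G)) = (n-1)/n$ used in tests; any
discrepancy with an $n$-denominator choice is $O(1/n)$. Heterozygote
dosage is 1, not dropped, because near-inbred lines retain residual
heterozygosity. Zero-variance columns are dropped with a warning.

## GBLUP

The prediction model is $y = \mu + g + e$ with
$g \sim N(0, G\sigma^2_g)$ and $e \sim N(0, I\sigma^2_e)$, fitted two
ways:

* **Gibbs sampler** (the study's estimation route): blocked Gibbs in the
  eigenbasis of the observed block of $G$, one rotation up front so each
  sweep is $O(n)$. Both variances carry scaled-inverse-$\chi^2$ priors
  with $\nu_0 = 5$ and scale set so the prior mode equals half the sample
  phenotypic variance — the default rule of the Bayesian regression
  software the study used, which it invoked with defaults. Defaults are
  12,000 iterations, 2,000 burn-in, no thinning; GEBVs are posterior
  means over the post-burn-in samples (the study does not say means or
  modes; means are declared here).
* **Eigendecomposition REML**: deterministic one-dimensional REML over
  $\lambda = \sigma^2_g/\sigma^2_e$ in the same eigenbasis, used both as
  a fast engine and as the independent oracle for the sampler in tests.

Unobserved or masked lines stay inside the joint prior; their GEBVs are
the conditional means through the genomic covariances,
$\hat g_u = \lambda\,G_{uo}(I + \lambda G_{oo})^{-1}(y - \hat\mu)$, which
for a Gaussian model is identical to post-hoc prediction (this
equivalence is itself a test). Eigenvalues of $G$ are floored at
$10^{-8}$ times the largest; matrices that are indefinite beyond that
tolerance raise an error advising a diagonal jitter.

## Cross-validation design

`buildNaSchemes()` reproduces the year-structured masking table: for a
masking fraction $f$ the test set is a uniform sample without replacement
of $\mathrm{round}(f\cdot\text{cohort})$ target-year lines (round half
up, which reproduces the published 28/56/140 test counts from a 280-line
cohort; how the original rounded the 270-line cohorts is not stated) and
the training set is everything else. $f = 1$ is the deterministic
forward-prediction scenario with no repeats. Per-repeat seeds are
`seed + repeat_index` for auditability. Skip-year schemes drop one
further cohort from training. Predictive ability is the Pearson
correlation of test-set GEBVs with test-set yearly BLUPs, computed per
run; scenario summaries average run-level correlations and never pool
pairs across runs.

## Kinship and structure diagnostics

The maximum realized kinship coefficient of test line $i$ is
$\max_j G_{ij}$ over training lines $j$, averaged over the test set.
PCA uses the same centered-and-scaled matrix as the GRM — the original's
PCA preprocessing is unstated, so this is the one place where results
may deviate from it in the second decimal — and reports percent variance
explained normalized over all components.

## Selection tracking

`gsVsPs()` compares, over the advanced lines only, the correlation of
preliminary-trial GEBVs with advanced-trial BLUPs against the correlation
of preliminary-trial BLUPs with advanced-trial BLUPs. Quadrant tracking
classifies advanced lines against the full-cohort mean BLUP and mean (or
75th-percentile) GEBV; "above" is the non-strict $\ge$ (the original does
not state strictness), and the advanced-subset mean BLUP is emitted as
the secondary threshold because both vertical lines appear in the
original displays. The NA50 tracking variant splits each cohort into two
random halves and takes every line's GEBV from the single fit in which
it was masked, so no prediction conditions on its own phenotype.

## The synthetic generator

`simulateCohorts()` draws an inbred founder panel (allele frequencies
uniform in `maf_range`), then builds yearly cohorts by crossing two
randomly chosen parents — founders or, from the second year on, an
earlier-cohort line with probability 0.5 per parent — followed by
`selfing_generations` (default 5, emulating F~3:6~ inbreds) of
single-seed-descent selfing, leaving residual heterozygosity of about
$0.5^{5}$ per initially heterozygous site. True breeding values are sums
of minor-allele QTL dosages times standard-normal effects.
`simulateTrial()` lays the cohort out in an augmented design (checks once
per incomplete block) or alpha lattice, adds line-by-location deviations,
an exact AR1xAR1 Gaussian field built from the Kronecker structure of the
two correlation matrices (Cholesky factors applied to iid normals), and
iid noise solving the plot-level calibration
$\sigma^2_e = \sigma^2_G(1-h^2)/h^2 - \sigma^2_{GE} - \sigma^2_{sp}$
(an error if negative). All randomness flows from one seed through named
substreams (founders, cohorts, QTL, GxE, fields, noise, advancement, CV,
Gibbs), so stages are independently reproducible.

Default conditions mirror the study system: four cohorts of
280/280/270/270 lines, 10 incomplete blocks with replicated checks,
eight locations, plot-level $h^2$ 0.5, G$\times$E-to-genetic variance
ratio 0.5, spatial-to-genetic ratio 0.3 with $\rho = 0.4$ on both axes.
The founder pool defaults to 200 inbreds — the scale a program making on
the order of a thousand crosses a year implies, and the value used for
the generator's frequency-calibration checks. Markers default to 1,000,
a deliberate desk-scale stand-in for the ~27k genotyping-by-sequencing
panel; tests and the acceptance script size their own populations
(n = 150 to 1,000 lines) to keep full runs in minutes on one CPU.

**What the generator does not emulate.** G$\times$E deviations are iid by
line and location; real interaction has year-level structure (check
re-ranking across seasons) that iid noise cannot produce. There is no
dominance or epistasis, no genotyping error, no pedigree beyond the
recorded parent pair, and selection operates on yield alone. One
consequence deserves emphasis: because later-cohort parents are drawn
from earlier cohorts, every test-year line has parents and/or offspring
in the training set no matter how much of its own cohort is masked, so
train-test kinship — and with it predictive ability — is nearly invariant
to the masking fraction. The decline of predictive ability from NA10 to
NA90 observed on the real program, which rests on within-year kinship
exceeding cross-year kinship, is therefore not reproduced by this
crossing design; the corresponding pipeline property is exercised, but a
passing prediction run here demonstrates correct masking mechanics, not
the real-data kinship gradient.

`simulateAdvancement()` needs a noise model for the later-stage
phenotypes that drive repeated truncation; since the advancement record
format carries none, the function takes the truth set and an `h2` and
regenerates phenotypes as true breeding value plus fresh noise, retaining
the top `keep_fraction` (default 0.5) each subsequent year.

## Reproducibility surface

`scripts/acceptance.R --seed N --out results/acceptance.json` recomputes,
from scratch at the given seed: the published train/test scheme sizes,
the GRM diagonal identity, Gibbs-vs-REML and chain-repeatability GEBV
correlations, heritability recovery at $h^2 \in \{0.3, 0.5, 0.8\}$
(n = 800), AR1 correlation recovery on 30x10 fields, NA10/NA50/NA90/NA100
predictive abilities on the four-cohort benchmark, kinship and PCA
summaries, and the genomic-vs-phenotypic comparison on simulated
advancement. Every number in the output is computed at run time by the
package functions.
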
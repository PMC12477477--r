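---
title: "Methods: from abundance tables to compound association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from abundance tables to compound association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizolink)
```

rhizolink analyses genus- or OTU-level community tables from rhizosphere
soil surveys: per-sample diversity, between-sample structure, constrained
ordination against soil environmental factors, taxon co-occurrence, and —
the package's centrepiece — grey relational analysis (GRA) ranking taxa by
how closely their abundance profile follows a measured compound
concentration. This vignette records the models, the tunable parameters and
their defaults, the numerical conventions, and the design choices that were
genuinely open.

## Grey relational analysis

GRA compares the *shape* of each characteristic series (a taxon's abundance
across observation points) with a parent series (the compound concentration
at the same points). It makes no distributional assumptions and is usable at
very small numbers of points — here three pooled origins — where correlation
tests are essentially powerless. The steps:

1. **Normalization.** Each series, parent included, is divided by its own
   mean (`mean_normalize()`), so all series are dimensionless with mean 1.
   Mean normalization tolerates zero entries (abundances of 0.005% occur in
   real genus tables); only the series mean must be positive. Initial-value
   and min–max normalization are available
   (`normalization = "initial"`/`"minmax"`) but are not the default: on the
   packaged survey fixture only mean normalization reproduces the published
   coefficient table, and it is the variant that keeps the analysis exactly
   invariant to each series' measurement scale.
2. **Differences.** $\Delta_i(k) = |x_0'(k) - x_i'(k)|$ for series $i$ at
   point $k$, with the extrema $\Delta_{\min}$ and $\Delta_{\max}$ taken
   globally over *all* series and points (not per series — a per-series
   convention changes every coefficient and does not reproduce the
   published values).
3. **Deng coefficient.**
   $\xi_i(k) = \dfrac{\Delta_{\min} + \rho\,\Delta_{\max}}
                     {\Delta_i(k) + \rho\,\Delta_{\max}}$
   with resolution coefficient $\rho \in (0,1]$, default $0.5$. $\xi$ lies
   in $(0,1]$ and equals 1 exactly where $\Delta_i(k) = \Delta_{\min}$.
   Larger $\rho$ compresses the spread of coefficients; the package checks
   numerically that raising $\rho$ raises every off-minimum coefficient.
4. **Degree and ranking.** The grey relational degree is the unweighted mean
   $r_i = \mathrm{mean}_k\,\xi_i(k)$; series are ranked by decreasing $r_i$
   with ties broken lexicographically. Weighted degrees (entropy or AHP
   weights) are out of scope.

Degenerate case: if every series coincides with the parent,
$\Delta_{\max} = 0$ and the coefficient quotient is 0/0; the package defines
$\xi \equiv 1$ there, the limit as the series approach the parent.

Rounding to 3 decimals happens only in `gra_rank_report()` and
`gra_coefficient_report()`; all internal math is full precision.

## The worked example shipped with the package

`inst/extdata` carries the genus-level relative abundances of a rhizosphere
soil survey of *Zanthoxylum nitidum* from six origins in southern China,
pooled into three origin pairs, together with the nitidine chloride content
(the species' pharmacopoeial quality marker) per pooled origin and the
per-sample soil properties. Pooling is the arithmetic mean of the member
samples' percentages (`pool_groups()`); the per-sample file lets the tests
confirm the pooled cells cell-by-cell. Running `grey_relation()` on this
fixture reproduces the survey's published coefficient table and ranking
(Rudaea first at degree 0.762, Lacibacterium last at 0.481), which the
acceptance script recomputes end to end.

## Alpha diversity

`alpha_report()` mirrors the standard per-sample survey table: total reads,
observed richness, singletons/doubletons, Shannon, Simpson, Chao1, ACE and
Good's coverage. Conventions, chosen where the field has more than one:

* **Shannon** uses the natural log (nats).
* **Simpson** is reported as the *dominance* form
  $D = \sum n_i(n_i-1)/(N(N-1))$ — higher means less diverse — matching the
  magnitude (~0.004–0.04) such survey tables print.
* **Chao1** defaults to the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, finite when $F_2 = 0$; the classic
  $F_1^2/(2F_2)$ form is behind `bias_corrected = FALSE`.
* **ACE** uses the Chao–Lee estimator with the conventional rare/abundant
  threshold of 10. When every rare taxon is a singleton the ACE coverage is
  0 and the estimator is undefined; the function falls back to Chao1 with a
  warning rather than returning infinity.

## Beta diversity and clustering

Bray–Curtis and presence/absence Jaccard go through `vegan::vegdist()`; a
pair of all-zero samples (0/0) is defined as distance 0 with a warning.
UniFrac is computed in-package by branch partition over an `ape` tree:
unweighted is unique-branch-length over union-branch-length; weighted is
$\sum_b L_b\,|p_{ib}-p_{jb}|$ over branch abundance masses, normalized by
default so it lies in [0, 1]. Unweighted is the default (`weighted = FALSE`)
since survey reports that say only "UniFrac" conventionally mean the
unweighted form. The tests check both forms against an independent
path-enumeration oracle and picante. `upgma()` (average linkage via
`hclust`) provides the dendrogram that accompanies distance heatmaps; only
the clustered matrix and leaf order are produced — graphics are left to the
caller.

## The gradient-length gate and RDA

`dca_axis_length()` runs DECORANA (`vegan::decorana`, 26 detrending
segments, Hill's nonlinear rescaling) and returns the first-axis length in
SD units of species turnover. Below ~3 SD species responses are close to
linear and RDA is the appropriate constrained method; `rda_gated()`
automates the check and annotates the result. A table in which every sample
has identical composition has no gradient and returns length 0 directly.

`rda_fit()` regresses the (transformed) community matrix on the
standardized factors and eigendecomposes the fitted covariance
(`vegan::rda`). The species transform defaults to **Hellinger** (square
root of relative abundances), the standard way to make abundance data
behave in a linear ordination; `"none"` reproduces textbook RDA and is the
setting under which the test suite verifies the decomposition against a
from-scratch SVD oracle at 1e-9, together with exact variance conservation
(constrained + unconstrained = total). Scores are reported in scaling 2
(correlation biplot), the scaling under which `interpret_rda()`'s reading
rules are valid: an acute angle between a sample's site vector and a factor
arrow means positive association, obtuse negative, and factors are ordered
per sample by the magnitude of the scalar projection of the sample point
onto each arrow. With as many factors as samples the model saturates
(constrained fraction 1 by construction); the function warns rather than
refuses, since saturated RDA biplots are still read qualitatively in survey
work.

## Co-occurrence network

`correlation_network()` keeps the `top_n = 100` most abundant taxa and
tests all pairs two-sidedly at `alpha = 0.05`, Spearman by default (robust
for compositional abundances; Pearson available). No multiplicity
correction is applied by default — the edge list mirrors the marginal
"p < 0.05" filter such figures conventionally use — and a
Benjamini–Hochberg option exists for principled analyses. Constant taxa
have undefined correlation; their pairs are skipped with a warning. Under
an independent Gaussian null the empirical edge rate matches the nominal
level (checked by simulation in the tests).

## The synthetic community generator

`simulate_community()` exists so every downstream stage is testable with
known ground truth. The generative model:

* baseline taxon profile from a symmetric Dirichlet
  (`base_concentration = 0.3`, giving the uneven genus profiles typical of
  soil);
* each environmental factor (defaults: pH strongest at 1.0, then sand 0.6,
  organic matter 0.4, altitude/clay 0.3, silt 0.2, in log-abundance shift
  per SD of the factor) shifts latent log-abundances through per-taxon
  standard-normal loadings; factors are reported in realistic natural units
  (pH ~5.5 ± 1.2, organic matter ~34 ± 14 g/kg, ...);
* `n_tracking_taxa = 3` taxa co-vary through a shared latent driver
  (loading 1.5) — taxa that "track a compound" must co-vary with one
  another, otherwise no individual taxon resembles their blended signal;
* multinomial sampling at `depth = 60000` reads per sample over
  `n_taxa = 300` taxa and `n_samples = 6`, matching the scale of a
  six-origin genus-level survey;
* the compound is the weighted (positive weights) sum of the tracking
  taxa's realized relative abundances, interpolated toward a flat profile
  by `1 - tracking_strength`, plus Gaussian noise (`noise_sd`), then
  rescaled **multiplicatively** into a realistic percent range. The rescale
  is multiplicative rather than min–max because mean normalization — the
  GRA default — is invariant to scale but not to shift; an affine shift
  would distort the planted shape the recovery tests rely on.

All randomness flows from the single integer seed through
`withr::with_seed()`; no global state is touched. `simulate_gradient()`
additionally provides unimodal Gaussian-response communities along an
explicit gradient whose `turnover` parameter (gradient length in tolerance
units) drives the DCA gate tests from both sides.

What the generator does *not* emulate: read-level error, chimeras,
taxonomic misassignment, compositional correlation induced by closure, or
spatial autocorrelation between samples. Passing the planted-signal tests
therefore shows the estimators recover structure the model actually
plants — not that they are robust to everything real surveys contain.

## Problem sizes used in the test suite

The invariant sweeps use 1,000 random count vectors (alpha), 10–15
five-sample instances (distance oracles), and 50 seeded replicates each for
the two planted-signal recovery properties (6–8 samples, 40 taxa, 2,000
reads — small communities keep the suite quick while leaving the planted
effects at realistic strength; recovery is required in at least 45 of 50
replicates, i.e. 90%). The full suite runs in well under a minute.

## Known limitations

* CCA (the unimodal branch of the gradient gate) is not implemented; the
  gate only reports which family of methods is indicated.
* GRA degrees are unweighted means over points; with only three pooled
  points a single aberrant point moves a degree by up to 1/3 of its range.
* The co-occurrence network is plain pairwise correlation: it inherits the
  compositionality caveats of relative-abundance data (no SparCC-style
  correction).
* `read_newick()` accepts any `ape`-parseable Newick tree; non-ultrametric
  or zero-length branches are allowed and flow into UniFrac as given.
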
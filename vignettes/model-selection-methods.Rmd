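---
title: "Selecting point-process models for forest stem maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting point-process models for forest stem maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemPPM)
```

## The scientific problem

Mapped forest plots record the coordinates of every stem of every species.
Almost all tropical tree species are spatially aggregated, and two very
different mechanisms produce aggregation: *dispersal limitation* (seeds
recruit near their parents, producing clusters at the scale of typical
dispersal distances) and *environmental heterogeneity* (survival varies
across the plot, producing broad intensity gradients). stemPPM implements a
model-selection approach to disentangle them: each species' pattern is
confronted with three candidate point processes,

* **IPP** — inhomogeneous Poisson process: points independent, intensity
  $\lambda(x, y)$ varies across the plot (pure heterogeneity);
* **HPCP** — homogeneous Poisson cluster (Thomas) process: Poisson parents
  of intensity $\kappa$, Poisson($\mu$) offspring displaced from their
  parent by an isotropic Gaussian with standard deviation $\sigma$ (pure
  dispersal limitation, mean cluster size $\approx 2\sigma$);
* **IPCP** — inhomogeneous Poisson cluster process: Thomas clusters whose
  realized intensity is modulated by $\lambda(x, y)$ (both mechanisms).

The winner per species, and the association between winners and the
species' dispersal syndromes (autochorous, anemochorous, zoochorous with
small / medium / large fruits), are then examined with contingency-table
and rank statistics.

## Summary statistics

The workhorse is Ripley's K: $\lambda K(r)$ is the expected number of
further conspecifics within distance $r$ of a typical individual, with
$K(r) = \pi r^2$ under complete spatial randomness. We estimate

$$\hat K(r) = \frac{|W|}{n(n-1)} \sum_{i \ne j} 1(d_{ij} \le r)\, e_{ij},$$

where $e_{ij}$ is an edge-correction weight. The package implements the
translation correction for rectangular windows,
$e_{ij} = |W| / ((W_x - |dx_{ij}|)(W_y - |dy_{ij}|))$, which is exactly
unbiased on rectangles, plus the uncorrected estimator ($e_{ij} = 1$) kept
for oracle tests. Translation was chosen because it is exact and needs no isotropic-weight
geometry. Duplicate coordinates are legitimate census data: pairs at
distance zero count from $r = 0$ on, and no jitter is applied.

The dimensionless aggregation statistic $K(r)/\pi r^2$ (1 under randomness,
above 1 when aggregated) is summarised per syndrome group as a mean
$\pm 1$ SE profile across species, on a grid every 10 m. Because the
statistic is undefined at $r = 0$, the profile grid is 10, 20, ..., 250 m.

For the inhomogeneous models, the intensity-reweighted form

$$\hat K_{\mathrm{inhom}}(r) = \frac{1}{|W|} \sum_{i \ne j}
\frac{1(d_{ij} \le r)\, e_{ij}}{\hat\lambda(x_i)\, \hat\lambda(x_j)}$$

is used. When $\hat\lambda$ is estimated from the pattern itself, the value
at each data point is the *leave-one-out* kernel estimate — the point's own
kernel contribution is subtracted — which removes the dominant positive
bias of self-inclusive plug-in. A consequence worth documenting: with a
constant surface $\lambda = n/|W|$, $\hat K_{\mathrm{inhom}}$ equals
$(n-1)/n$ times the homogeneous $\hat K$; the reduction tests use this
convention. Leave-one-out intensities of isolated points at small
bandwidths can underflow to zero; they are floored at $10^{-8} \, n/|W|$ so
the reweighting stays finite (such candidate fits lose on AIC regardless).

## Intensity estimation

Heterogeneity surfaces are estimated from the pattern of trees themselves —
not from environmental covariates — by isotropic Gaussian kernel smoothing
with bandwidth $h$ (the kernel standard deviation, in metres). Each kernel
is divided by the fraction of its mass inside the window (uniform
per-kernel renormalisation), so the surface integrates to $n$ exactly; for
a Gaussian kernel on a rectangle that fraction is a closed-form product of
normal CDFs, so intensities at data points are evaluated exactly rather
than from the raster. The raster default is a 5 m cell (a 1000 × 500 m plot
becomes 200 × 100 cells), at most half the smallest default bandwidth.

The bandwidth is not optimised within a fit: it is a *candidate* over the
geometric ladder $\{12.5, 25, 50, 100, 200\}$ m, and model selection
charges it as one free parameter. The Gaussian kernel matches the Gaussian
offspring displacement used throughout; published per-group summaries for
these data report only mean selected bandwidths, never a candidate set, so
the ladder — spanning within-cluster to plot-quarter scales — is this
package's default.

## Fitting and selection

Cluster parameters are estimated by minimum contrast against the Thomas
closed form $K(r) = \pi r^2 + (1 - e^{-r^2/4\sigma^2})/\kappa$:

$$D(\kappa, \sigma) = \sum_{r \in G} \left(\hat K(r)^{1/4} -
K(r; \kappa, \sigma)^{1/4}\right)^2,$$

with the variance-stabilising exponent $q = 1/4$, on a fitting grid $G$ of
128 equal steps from 0 to a quarter of the window's short side (125 m on
the default plot). Optimisation is bounded L-BFGS-B on the log scale,
restarted from a 3 × 3 lattice of method-of-moments starts
($\kappa_0 = n / (|W| \mu_\mathrm{guess})$ with
$\mu_\mathrm{guess} \in \{2, 5, 20\}$; $\sigma_0 \in \{5, 15, 50\}$ m) with
box constraints $\kappa \in [10^{-7}, 1]$, $\sigma \in [0.5, 500]$ m; a fit
that fails in every start is flagged, never a silent NaN. IPP has no shape
parameters given its surface: its discrepancy is the contrast of
$\hat K_{\mathrm{inhom}}$ against $\pi r^2$. IPCP runs the Thomas contrast
against $\hat K_{\mathrm{inhom}}$.

Candidates are scored with a residual-based AIC,

$$\mathrm{AIC} = m \log(D/m) + 2k,$$

the Gaussian-residual form with $m$ the grid length, which is scale-free
across models whose empirical K differs (homogeneous vs reweighted); the
raw form $D + 2k$ is available behind a switch. Parameter counts are the
selection's main free choice and are stated openly: IPP $k = 1$ (its
bandwidth), HPCP $k = 2$ ($\kappa, \sigma$), IPCP $k = 3$ ($\kappa,
\sigma$, bandwidth) — the nonparametric surface is charged exactly one
parameter. The candidate set is one IPP and one IPCP fit per bandwidth plus
the single HPCP fit (the homogeneous Poisson process itself is *not* a
candidate; the comparison is deliberately between the three mechanistic
models). Exact AIC ties go to the less complex class, then to the smaller
bandwidth. $\sigma$ is reported only when a cluster class wins.

## Cross-species inference

Winners are cross-tabulated as a 3 (class) × 5 (syndrome group) table.
Independence is tested by the Fisher exact test with a Monte-Carlo p-value:
10,000 tables are drawn with fixed margins (Patefield's algorithm via
`r2dtable`), the statistic is each table's multivariate-hypergeometric
probability, and $p = (1 + \#\{\text{simulated} \le \text{observed}\}) /
(B + 1)$ — the add-one convention of the standard statistical-environment
implementation, against which the tests cross-check it, alongside
exhaustive enumeration on small tables. Cell
departures are reported as *adjusted* standardized residuals
$(O - E)/\sqrt{E (1 - \text{row}/N)(1 - \text{col}/N)}$, which are
unit-variance under independence so the conventional 2 / 4 significance
thresholds apply; raw Pearson residuals would not support those cut-offs.

Cluster sizes are compared across groups with the Kruskal–Wallis test
(midranks, tie correction) and pairwise with two-sample Wilcoxon rank-sum
tests, $W = \sum \text{ranks}(a) - n_a(n_a+1)/2$, exact for small tie-free
samples. The directional hypotheses (autochorous and anemochorous clusters
smaller than zoochorous) default to one-sided "less". Species whose best
model is IPP define no $\sigma$ and enter the contingency analysis only.
Published summaries of these comparisons are sometimes labelled signed-rank
tests while reporting two-sample W statistics; the two-sample rank-sum test
is what reproduces such statistics and is what the package implements. Per-cell
$\sigma$ summaries report mean $\pm$ SE *across species*, the only
interpretation consistent with cells containing a handful of species.

## The synthetic community

Census-scale stem-map data are access-controlled, so the package ships a
generator whose defaults emulate the analysis conditions: a 1000 × 500 m
window, 229 species, syndrome groups in proportions 8/24/112/58/27,
log-normal abundances (median 60, sdlog 0.8 — the heavy right tail of
tropical plots) truncated at the 20-individual census threshold, per-group
model-class mixtures equal to the published contingency frequencies, and
log-normal cluster scales (median 12 m, sdlog 0.4, so mostly
$\sigma \le 25$ m). Trend surfaces for inhomogeneous species are mixtures
of 3–10 Gaussian bumps with scales of at least 50 m on a positive baseline:
heterogeneity (≥ 50 m) and dispersal limitation (tens of metres) are
identifiable *by construction*, mirroring the scale separation the method
presumes. The IPCP is generated by location-dependent thinning of offspring
(not parents); either construction yields the product-form intensity the
fitted model assumes, and thinning modulates the realized intensity exactly
as fitted. Parents are simulated on the window dilated by $4\sigma$
(> 99.99% of offspring mass), so edge clusters are complete.

Every species carries a ground-truth ledger record (class, $\sigma$, trend
scale, abundance), and a top-level seed expands into per-species sub-seeds
by stable hashing of the species label, so adding a species never perturbs
the others. What the generator does **not** emulate: species interactions,
density-dependent mortality, covariate-driven (soil, topography) intensity,
or any real species list — passing tests demonstrate estimator and
selection correctness under the stated mechanisms, not fidelity to any
particular forest.

Three presets are provided: `paper_like` (the defaults), `null_uniform`
(identical $\sigma$ distribution and class mixture in every group — the
null for type-I calibration of the rank tests) and
`anemochorous_clustered` (an HPCP-heavy anemochorous group, for power
checks of the contingency test).

## Numerical choices and validation sizes

* Pairwise distances and translation weights are computed once per pattern
  and reused across all bandwidths and grids (sorted cumulative sums, so a
  K evaluation is a binary search).
* Validation problem sizes were chosen to make Monte-Carlo error small at
  desk scale: estimator unbiasedness and closed-form agreement use 200
  replicates at $n \approx 500$–1000; $\sigma$ recovery uses 50 replicates
  per generating class at $n \approx 500$ (median relative error under
  25%); selection consistency uses 100 replicates per scenario, with the
  "well-separated" scenarios defined as strong clustering
  ($\kappa = 2 \times 10^{-4}$ parents/m², $\mu = 10$, $\sigma = 10$ m,
  flat intensity) versus broad-trend clusters ($h = 100$ m bumps,
  $\sigma = 8$–10 m). Recovery for inhomogeneous cluster species is
  measured on the AIC-selected fit — the $\sigma$ the pipeline reports —
  because a kernel at the generating trend scale partially absorbs tight
  clusters into the surface (each cluster inflates its own neighbourhood's
  $\hat\lambda$ by order $\mu/(2\pi h^2 \bar\lambda)$), deflating
  within-cluster pair weights and biasing a fixed-bandwidth $\hat\sigma$
  low; selection migrates to larger bandwidths where that absorption is
  negligible. Type-I calibration of the Kruskal–Wallis stage runs
  100 `null_uniform` communities of 15 species; since model selection is
  orthogonal to that test's null, each species' $\sigma$ is taken from its
  homogeneous cluster fit, which keeps the calibration exact for the
  rank-test stage while remaining tractable.
* A homogeneous-cluster fit near the Poisson boundary drives
  $\sigma$ toward its upper bound (a Poisson process is a cluster process
  whose clusters exceed the plot); the bounds above keep such fits finite
  and the AIC comparison meaningful.

## Known limitations

* Minimum contrast is not likelihood-based; no standard errors accompany
  $\hat\kappa, \hat\sigma$ beyond across-species spread.
* An IPP realization is frequently indistinguishable from a weak cluster
  process at plot scale (the converse of the $\sigma$-larger-than-the-plot
  remark above); selection consistency is only claimed for well-separated
  scenarios.
* The IPCP candidate with a near-flat surface nests the HPCP, so HPCP
  recovery rates sit well below IPCP recovery rates at moderate abundance —
  visible in the consistency tests and inherent to the candidate set.
* No pair-correlation function, no isotropic correction, no Matérn or
  log-Gaussian Cox alternatives, and no multiple-testing correction across
  the $\sigma$ comparisons (deliberately: each directional hypothesis is
  reported on its own).

## A worked example

```{r example, eval = FALSE}
cfg <- scenarioPreset("paper_like", nSpecies = 20)
com <- generateCommunity(cfg, seed = 1)
out <- runAnalysis(com$stems, com$traits, nSims = 10000, seed = 1)
out$contingency
out$fisher$p_value
head(out$results)
```
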
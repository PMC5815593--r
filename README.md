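# stemPPM

Point-process model selection for forest stem maps.

Fully mapped forest plots (one row per stem: species, x, y) show that
conspecific aggregation is the rule, and two mechanisms can produce it:
**dispersal limitation** (offspring recruit near parents, clusters at the
scale of dispersal distances) and **environmental heterogeneity** (broad
intensity gradients from habitat variation). stemPPM disentangles them per
species by fitting and comparing three point processes:

| model | mechanism | parameters charged |
|-------|-----------|--------------------|
| IPP   | inhomogeneous Poisson: independent points, intensity λ(x, y) varies | k = 1 (kernel bandwidth h) |
| HPCP  | homogeneous Poisson cluster (Thomas): parents κ, Poisson(μ) offspring, Gaussian displacement σ | k = 2 (κ, σ) |
| IPCP  | Thomas clusters modulated by λ(x, y) | k = 3 (κ, σ, h) |

Patterns are summarised by Ripley's K (translation edge correction;
intensity-reweighted form for the inhomogeneous models, with leave-one-out
Gaussian-kernel intensities). Cluster parameters come from minimum contrast
against the Thomas closed form K(r) = πr² + (1 − e^(−r²/4σ²))/κ with the
variance-stabilising exponent q = 1/4, and candidates are ranked by a
residual-based AIC = m log(D/m) + 2k. The mean cluster diameter is reported
as 2σ. Across species, best-model frequencies are cross-tabulated against
dispersal syndromes (autochorous, anemochorous, zoochorous small / medium /
large fruits) and tested with a Monte-Carlo Fisher exact test (fixed
margins, 10,000 tables), adjusted standardized residuals, Kruskal–Wallis
and Wilcoxon rank-sum comparisons of σ.

The package also ships simulators for all four generating processes
(CSR / IPP / HPCP / IPCP) and a synthetic multi-species community generator
with a ground-truth ledger, used by the test suite for estimator
unbiasedness, parameter-recovery and selection-consistency checks.

Audience: ecologists analysing mapped plots (forest-dynamics censuses) and
anyone needing reproducible Thomas-process fitting and selection on
rectangular windows without further dependencies.

## Worked example

```r
library(stemPPM)

# a synthetic 20-species community with the published syndrome structure
cfg <- scenarioPreset("paper_like", nSpecies = 20)
com <- generateCommunity(cfg, seed = 1)
out <- runAnalysis(com$stems, com$traits, nSims = 10000, seed = 1)

out$contingency
#>      autochorous anemochorous zoo-small zoo-medium zoo-large
#> IPP            0            0         0          0         0
#> HPCP           0            1         9          0         2
#> IPCP           0            0         4          3         1

round(out$fisher$p_value, 3)
#> [1] 0.12

subset(out$results, best_model != "IPP")[1:3, c("species", "group", "best_model", "sigma")]
#>   species      group best_model     sigma
#> 1   sp001 zoo-medium       IPCP  9.814797
#> 2   sp002  zoo-small       HPCP 26.383676
#> 3   sp003 zoo-medium       IPCP  8.685204
```

The contingency table counts species by best-fitting model class and
syndrome group; the Fisher p-value tests their independence (here, with 20
null-ish species, no association); `sigma` is the fitted cluster scale in
metres (mean cluster size ≈ 2σ), defined only for cluster-model winners.

The published 229-species census table is packaged:

```r
tab <- bciSyndromeModelCounts()
contingencyShares(tab)$total          # IPP 17.5, HPCP 19.7, IPCP 62.9 (%)
fisherExactMC(tab, 10000, seed = 1)$p_value
#> [1] 0.0414
contingencyResiduals(tab)["HPCP", "anemochorous"]
#> [1] 2.87  (> 2: anemochorous species are HPCP-enriched)
```

## Layout

- `R/` — S4 classes (`Window`, `PointPattern`, `IntensitySurface`,
  `KEstimate`, `ModelFit`, `ModelSelection`) and the estimators, fitters,
  simulators, inference and pipeline code.
- `vignettes/model-selection-methods.Rmd` — the model, estimators, design
  decisions and known limitations.
- `inst/extdata/` — the packaged census contingency counts.
- `tests/testthat/` — unit, property and acceptance tests with brute-force
  and enumeration oracles.
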
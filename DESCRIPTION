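Package: stemPPM
Title: Point-Process Model Selection for Forest Stem Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterise mapped tree distributions (stem maps) with
    Ripley's K function, estimate nonparametric intensity surfaces by Gaussian
    kernel smoothing, fit inhomogeneous Poisson (IPP), homogeneous Poisson
    cluster (HPCP) and inhomogeneous Poisson cluster (IPCP) point-process
    models by minimum contrast, and select among them with a residual-based
    AIC. Includes simulators for all four generating processes, a synthetic
    multi-species community generator with known ground truth, and
    cross-species inference: syndrome-by-model contingency tables, a
    Monte-Carlo Fisher exact test, adjusted standardized residuals, and
    Kruskal-Wallis and Wilcoxon comparisons of fitted cluster scales.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
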
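Package: boldvar
Title: Spatiotemporal Variance Analysis of Intrinsic Placental and Fetal
    Brain BOLD MRI
Version: 0.1.0
Authors@R:
    person("Rowan", "Calder", email = "rcalder@example.org",
           role = c("aut", "cre"))
Description: Quantifies intrinsic (task- and challenge-free) blood
    oxygen level dependent (BOLD) signal fluctuations in the placenta and
    fetal brain from 4D echo-planar time series.  Provides synthetic 4D
    phantom and covariate-cohort generators with analytic ground truth,
    volume-of-interest preprocessing (frame propagation, inter-slice rigid
    motion correction with a normalized cross-correlation cost, temporal
    filtering and amniotic-fluid nuisance regression), the temporal-variance
    and spatial-variance summary statistics, and a heteroskedasticity-robust
    wild-bootstrap regression battery with gestational-age adjustment,
    congenital-heart-disease interactions, Benjamini-Hochberg false
    discovery rate control, covariate-adjusted Kolmogorov-Smirnov group
    comparison, histogram-moment tests and Welch t tests, orchestrated by a
    deterministic end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
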
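Package: dlchrom
Title: Dynamic Loop Chromatin Model on the Bond-Fluctuation Lattice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lattice Monte Carlo simulation of coarse-grained chromosomes with
    stochastic, finite-lifetime chromatin loops (the Dynamic Loop model) using
    the bond-fluctuation method. Provides equilibration and decorrelation
    diagnostics (integrated autocorrelation times by self-consistent
    windowing), gyration-tensor shape analysis, estimation of the entropic
    effective potential between two chromosome centers of mass by
    superposition rejection sampling, accepted-pair swelling, asphericity,
    mutual alignment and projected-density overlap statistics, and mapping of
    lattice units to physical units against FISH-style mean-square-distance
    curves.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
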
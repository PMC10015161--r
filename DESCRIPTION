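Package: topotest
Title: Exhaustive Constrained Tree-Topology Testing for Gene-Duplication Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dates gene duplications relative to speciation events by exhaustive
    maximum-likelihood evaluation of tree topologies. Enumerates every unrooted
    topology over a set of constrained operational taxonomic units (OTUs),
    scores each by maximum likelihood under an empirical amino-acid model with
    invariant sites and discrete-gamma rate heterogeneity (JTT+I+G4), applies
    resampling-based topology tests (approximately unbiased, Kishino-Hasegawa,
    Shimodaira-Hasegawa) via resampling of estimated log-likelihoods (RELL),
    ranks topologies by the scaled log-likelihood deficit, and classifies each
    topology into duplication-timing scenarios (duplication before or after a
    reference lineage split). Includes a sequence simulator under the same
    model family for fixture construction and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
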
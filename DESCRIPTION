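Package: lnpka
Title: Apparent pKa of Ionizable Lipids in Bilayers from Umbrella Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structure-based prediction of the apparent pKa (pKa^A) of
    ionizable lipids in lipid-nanoparticle-like bilayers. Provides
    umbrella-sampling window planning, reading and filtering of
    reaction-coordinate time series, a self-consistent 1-D weighted
    histogram analysis method (WHAM) solver for potentials of mean force
    (PMFs), PMF smoothing/baselining/replicate averaging, and the
    thermodynamic-cycle calculation of the membrane-induced pKa shift
    (delta pKa) and apparent pKa. An overdamped Langevin sampler over
    analytic membrane-like free-energy profiles generates synthetic
    biased datasets with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
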
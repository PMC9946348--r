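Package: msomResurvey
Title: Dynamic Multispecies Occupancy Models for Century-Scale Resurveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian dynamic multispecies occupancy modelling for
    paired historic/modern presence-absence resurveys. Provides a detection-history
    data model with support for heterogeneous historic survey modes, a synthetic
    resurvey generator with known truth, a marginalized (latent-incidence-summed)
    likelihood with community shrinkage priors sampled by adaptive
    Metropolis-within-Gibbs, convergence and WAIC diagnostics, posterior
    diversity-change metrics (richness change, Sorensen/Simpson/nestedness
    partition of temporal beta diversity, per-species occupancy change),
    occupancy-change sensitivity derivatives, and counterfactual decomposition of
    climate versus land-use impacts with quadrant classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    vegan,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
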
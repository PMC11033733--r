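Package: assemblage
Title: Null-Model Analysis of Gut Microbial Community Assembly in Longitudinal Cohorts
Version: 0.1.0
Authors@R: person("Calf Microbiome", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying deterministic versus stochastic community
    assembly in longitudinal microbiome studies. Implements checkerboard
    C-score standardized effect sizes against fixed-fixed binary null models
    (sequential swap and quasiswap), the modified Raup-Crick dissimilarity
    from a richness-preserving occupancy-weighted probabilistic null, a
    modified stochasticity ratio, PERMDISP contrasts of actual communities
    against null simulations, Levins niche-breadth ecotype classification
    (generalist/specialist/neutralist), Spearman co-occurrence networks with
    integrated-value-of-influence node ranking, and a two-state
    continuous-time Markov model of assembly-state transitions with
    covariate hazard ratios. Ships a synthetic longitudinal cohort generator
    with planted assembly regimes, ecotypes, and Markov dynamics so every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
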
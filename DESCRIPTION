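Package: palmvision
Title: Palm Fruit Colour and the Macroecology of Primate Colour Vision
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether the geographic distribution and
    diversification of primate colour-vision systems track the availability
    of conspicuous (reddish) palm fruits. Builds per-unit assemblage tables
    from occurrence and trait data with a fruit-colour classification rule;
    fits recursive observed-variable path models (structural equation
    models) by maximum likelihood with chi-square, CFI and RMSEA fit
    indices, backward elimination and modification indices; provides a
    richness-preserving permutation null and a progressive palm-richness
    delimitation analysis; fits simultaneous autoregressive (SAR) error
    models with Moran's I diagnostics on gridded assemblages; and supplies
    Mk-model ancestral state reconstruction, stochastic character mapping,
    trait-state lineage-diversity-through-time curves, and multi-state
    speciation-extinction (MuSSE) likelihoods. A seeded synthetic-data
    generator emulates the joint structure of the inputs so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
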
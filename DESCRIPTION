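Package: seedsel
Title: Spatial Selectivity Analysis of Single-Seed Removal Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing spatial selectivity in single-seed removal
    field experiments on regular grids of seed-offer devices. Implements
    Dixon's nearest-neighbour contingency-table segregation test generalised
    to the multidimensional space of eigenvalue-weighted, varimax-rotated
    principal component scores of microhabitat cover variables; randomization
    tests of used-versus-available microhabitat characteristics with pooled
    and grid-stratified nulls; join-count and Moran's I correlograms over
    distance classes with Monte-Carlo envelopes under complete spatial
    randomness and a heterogeneous distance-to-tree null model; binomial GLM
    analysis of deviance of removal intensity; and a synthetic-data generator
    that emulates the field protocol with known selection structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
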
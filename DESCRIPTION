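Package: frugnet
Title: Individual-Based Plant-Frugivore Interaction Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing individual-based seed-dispersal networks
    between focal plants and frugivore species along a range-expansion
    gradient. Standardizes camera-trap and DNA-barcoding interaction surveys
    by sampling effort (recorded area and time) and fuses them into one
    weighted adjacency matrix; finds modules by maximizing Barber's bipartite
    weighted modularity with a label-propagation algorithm (LPAwb+ and its
    multi-restart variant) and assesses significance against a
    connectance-preserving null ensemble; computes node topological roles
    (among-module connectivity c and within-module degree z); tests module
    composition against stand provenance with Pearson's chi-squared and
    adjusted residuals; screens plant traits by variance-inflation pruning and
    forward Wilks' lambda selection before linear discriminant analysis of
    module membership; and estimates per-plant viable-seed dispersal with a
    multiplicative effectiveness estimator, followed by AICc model selection,
    LMG relative-importance decomposition, Tukey post hoc group comparisons
    and within-stand contribution inequality rankings. A synthetic-data
    generator emulating the field design (three stands, stratified focal
    plants, two survey channels with known detection thinning) provides
    ground-truthed data for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
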
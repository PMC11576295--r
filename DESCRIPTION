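Package: ipvkit
Title: Item Pool Visualization for Multi-Questionnaire Comparisons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares psychological questionnaires that target a common
    construct by Item Pool Visualization (IPV): a single-factor confirmatory
    factor model over the pooled items defines the construct's core, a
    correlated-factor model over instrument or facet sub-pools defines the
    specific components, and per-item center distances (the proportional
    increase in explained item variance under the specific factor) locate
    items, facets and instruments relative to the core on nested radar maps.
    Ships a registry of four flourishing questionnaires (MHC-SF, PERMA-
    Profiler, Flourishing Scale, Wellbeing Conceptual Framework; 47 items),
    a maximum-likelihood CFA engine with Satorra-Bentler scaled test
    statistics and the usual fit indices (chi-square/df, RMSEA with 90% CI,
    SRMR, CFI, robust variants), a seeded Likert response simulator for a
    known population factor model, and deterministic SVG radar charts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
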
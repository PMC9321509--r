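Package: espmcr
Title: Ecological Security Patterns from Minimum Cumulative Resistance Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs ecological security patterns for a landscape from
    raster inputs: multi-factor ecological-sensitivity and ecosystem-service
    importance evaluation with Analytic Hierarchy Process (AHP) weighting and
    Saaty consistency diagnostics, ecological-source identification by
    natural-breaks classification with proximity merging and area filtering,
    comprehensive resistance surfaces by reclassification and weighted
    overlay, minimum-cumulative-resistance (MCR) cost distance and least-cost
    corridor networks, circuit-theory current flow for pinch-point detection,
    and five-class ecological-safety zoning with policy-area mapping. Includes
    a seeded synthetic-landscape generator so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
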
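Package: windcanopy
Title: Wind-Induced Canopy Displacement Effects on Light Interception and
    Photosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to study how wind-induced movement of a cereal canopy
    changes its light environment and daily carbon gain.  Generates
    rice-like triangle-mesh plants and 3x3 canopy stands, applies
    solid-body rotations that mimic steady and gusting wind displacement,
    computes per-triangle diurnal photosynthetic photon flux density
    (PPFD) by forward Monte Carlo ray tracing with periodic lateral
    boundaries, and scales leaf-level light to daily canopy carbon gain
    with a layer-parameterised non-rectangular hyperbola light response.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    pracma,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
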
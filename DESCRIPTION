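Package: rhizohair
Title: Structural Simulation of Root Hair Growth in Labelled 3D Soil Volumes
Version: 0.1.0
Authors@R:
    person("Rhizosphere", "Modelling", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A semi-stochastic, collision-avoiding tip-extension simulator
    that grows populations of root hairs from a root or planar surface into
    a labelled three-dimensional multi-phase soil volume (gaseous pore,
    hydrated textural, primary mineral and root phases). Includes generators
    for idealised sphere-packing (BCC/HCP) and correlated three-phase soil
    geometries, Weibull survival-analysis sampling of hair growth lengths,
    grain filtering by equivalent diameter, surface extraction with inward
    normals, Euclidean distance maps, and morphometric analyses: shell-binned
    total and fluid-coincident hair length profiles, bulk-control wet-length
    approximation, explicit-versus-control elevation, tortuosity and
    replicate statistics. A command-line interface orchestrates end-to-end
    scenario runs and parameter sweeps.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
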
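Package: nematoshell
Title: Active Nematic Vertex-Model Shells with Strain-Gated Morphogen Feedback
Version: 0.1.0
Authors@R: person("Maya", "Keller", email = "mkeller@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mechanochemical
    self-organization in regenerating epithelial shells. Implements a
    vertex model on closed curved surfaces with an exact lumen-volume
    constraint, a per-cell unit nematic (muscle-fiber) field with
    neighbor alignment and morphogen-gradient coupling, active
    contraction pulses, reaction-diffusion morphogen dynamics on the
    polygonal cell network with a strain-gated production term, T1
    topology changes, topological-defect detection with exact charge
    accounting on genus-0 shells, quantitative strain-profile and
    cell-shape-anisotropy analysis, and structure-tensor fiber
    orientation analysis for 2D intensity rasters. Includes generators
    for all synthetic inputs (spheroidal cell meshes, nematic defect
    patterns, fiber-texture images, event time series).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
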
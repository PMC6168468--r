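Package: spatialnet3d
Title: Hierarchical Anti-Hebbian Network Model of 3D Spatial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for the emergence of
    three-dimensional spatial representations (place, grid, border, plane,
    stack and other spatial cells) in a hierarchical network model of 3D
    navigation. Generates naturalistic volumetric flight trajectories and
    constrained planar trajectories, encodes heading through azimuth and
    pitch head-direction populations feeding oscillatory path integrators,
    and trains a lateral anti-Hebbian network (Hebbian/Oja afferent
    plasticity with Stent lateral inhibition) whose weights converge to the
    principal subspace of the path-integration input. Provides the full 3D
    spatial-map scoring suite: voxelized firing-rate maps, 3D/2D
    autocorrelograms, spatial information, hexagonal and square gridness,
    face-centered-cubic (FCC) symmetry score, border score, plane index,
    ellipsoid isotropy fits, shuffling-based significance thresholds, a
    cell-type classification cascade and eigen-spectrum band analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
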
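Package: physnet
Title: Growth, Scaling and Laplacian Spectra of Physical Networks
Version: 0.1.0
Authors@R:
    person("physnet", "maintainers", email = "physnet@example.org",
           role = c("aut", "cre"))
Description: Physical networks are made of volume-excluding objects
    embedded in space: extended nodes (neuron arbors, molecular strands,
    roots) connected by localized bonds. This package represents such
    systems as networks-of-networks on a periodic cubic lattice and
    provides a minimal growth model in which nodes are loop-erased random
    walk or straight-line trajectories grown until they hit the existing
    network; the closed-form scaling theory for total volume, node
    degrees and the degree-distribution exponent; estimators for the
    corresponding observables (fractal dimension, growth and tail
    exponents, degree-volume correlation, saturation scaling); the
    volume-normalized physical Laplacian with its perturbation-theory
    link to the layout Laplacian; and loaders, fixture generators and
    spectral reports for real connectome-style networks supplied as a
    weighted edge list plus node volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
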
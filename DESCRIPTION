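Package: backbonediff
Title: Correlated Diffusion Modelling and Programmable Generation of
    Protein Backbones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling of protein backbone structures with a
    correlated (polymer-structured) Gaussian diffusion process.  Provides a
    chain- and radius-of-gyration-constrained Gaussian prior over backbone
    coordinates with an exact whitening transform, forward noising and
    reverse-time (annealed Langevin) sampling including a low-temperature
    mode, a sub-quadratic random-graph message-passing denoiser trainable at
    desk scale with consensus synthesis of global coordinates from predicted
    inter-residue geometries, a composable conditioner framework (point-group
    symmetry, substructure clamping, pairwise distance restraints,
    optimal-transport shape guidance and generic classifier guidance),
    backbone structural statistics (radius of gyration, contact order,
    secondary-structure assignment, Kabsch superposition), PDB input/output,
    synthetic-structure generators, and a small command-line layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
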
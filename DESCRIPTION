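Package: cetrefine
Title: Constrained Single-Particle Refinement for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scalable single-particle cryo-electron tomography without
    sub-volumes or saved particle stacks: tilt-geometry pose composition,
    fully constrained and region-based projection refinement, per-particle
    contrast transfer function (CTF) handling and region-based CTF
    refinement, video-frame trajectory refinement with score-driven
    exposure weighting, constrained 3D classification from 2D projections,
    Fourier-space reconstruction with half-map FSC, and 3D particle
    picking. A bundled tilt-series simulator with known ground truth
    exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
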
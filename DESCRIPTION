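Package: rtetomo
Title: Optical Tomography with the Radiative Transfer Equation and
    Split Bregman TV-L1 Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of continuous-wave optical
    tomography in two dimensions based on the radiative transfer equation
    (RTE).  The forward problem is discretized with an upwind discontinuous
    Galerkin method on unstructured triangular meshes and a collocated
    direction set with the Henyey-Greenstein scattering kernel; the
    transport fixed point is solved by source iteration with optional
    matrix-free GMRES acceleration.  Sensitivities of boundary measurements
    with respect to the per-element absorption coefficient are computed by
    the adjoint method.  The absorption coefficient is reconstructed by a
    Levenberg-Marquardt iteration with mixed total-variation and L1
    regularization handled through the split Bregman scheme (lagged
    diffusivity for the smoothed TV term, shrinkage for the L1 term).
    Includes deterministic disk mesh generation, piecewise-constant
    phantoms with circular inclusions, multiplicative Gaussian measurement
    noise, and preset simulation experiments with a dual-mesh guard
    against the inverse crime.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
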
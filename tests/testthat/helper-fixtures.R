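# Shared small fixtures, built once per test run.

.fix_env <- new.env()

memo <- function(key, expr) {
  if (is.null(.fix_env[[key]])) assign(key, force(expr), envir = .fix_env)
  .fix_env[[key]]
}

# ~60-element disk with 8 directions: small enough for the direct
# global solve and finite-difference oracles
tiny_problem <- function() memo("tiny", {
  mesh <- mesh_disk(5, 60, seed = 2)
  grid <- build_angular_grid(8, 0.5)
  list(mesh = mesh, grid = grid,
       setup = dg_setup(mesh, grid),
       coeffs = optical_coefficients(rep(0.05, mesh$n_elements),
                                     rep(2, mesh$n_elements), mesh),
       units = place_boundary_units(mesh, 3, 3, grid))
})

# moderate mesh for quadrature/convergence style checks
medium_mesh <- function() memo("medium", mesh_disk(10, 800, seed = 3))

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))
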
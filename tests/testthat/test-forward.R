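test_that("the incident impulse is a single-direction hat on its source edge", {
  tp <- tiny_problem()
  src <- tp$units$sources[1, ]
  inf <- incident_profile(src, tp$mesh, tp$grid)
  expect_s3_class(inf, "rte_inflow")
  expect_equal(inf$kind, "hat")
  expect_equal(inf$peak, 1)                     # value 1 at the edge centre
  # support: only the source edge, only the source direction
  nz <- which(inf$moments != 0, arr.ind = TRUE)
  expect_setequal(unique(nz[, 2]), src$dir_index)
  expect_setequal(unique((nz[, 1] + 1L) %/% 2L), src$bedge)
  # hat moments integrate to |e|/4 against each edge basis function
  len <- tp$mesh$boundary_edges$length[src$bedge]
  expect_equal(inf$moments[2 * src$bedge - 1L, src$dir_index], len / 4)
  # an outflow direction is rejected
  bad <- src; bad$dir_index <- ((src$dir_index - 1 + 4) %% 8) + 1
  expect_error(incident_profile(bad, tp$mesh, tp$grid), "inflow")
})

test_that("iterative transport solutions match the directly assembled global system", {
  tp <- tiny_problem()
  inf <- incident_profile(tp$units$sources[1, ], tp$mesh, tp$grid)
  fd <- solve_rte_direct(tp$mesh, tp$grid, tp$coeffs, inf, setup = tp$setup)
  fg <- solve_rte(tp$mesh, tp$grid, tp$coeffs, inf, tol = 1e-12, setup = tp$setup)
  fs <- solve_rte(tp$mesh, tp$grid, tp$coeffs, inf, tol = 1e-11,
                  method = "source", setup = tp$setup)
  expect_lt(rel_err(fg$values, fd$values), 1e-8)
  expect_lt(rel_err(fs$values, fd$values), 1e-8)
  expect_true(all(is.finite(fg$values)))
})

test_that("zero inflow produces the identically zero field", {
  tp <- tiny_problem()
  f <- solve_rte(tp$mesh, tp$grid, tp$coeffs, inflow_zero(tp$mesh, tp$grid),
                 setup = tp$setup)
  expect_equal(max(abs(f$values)), 0)
})

test_that("a pure-absorption beam follows the Beer-Lambert law across the disk", {
  m <- mesh_disk(10, 3000, seed = 1)
  g <- build_angular_grid(32, 0)
  co <- optical_coefficients(rep(0.1, m$n_elements), rep(1e-9, m$n_elements), m)
  be <- m$boundary_edges
  inf <- inflow_constant(m, g, which(be$mid_x < 0), value = 1, dirs = 1L)
  f <- solve_rte(m, g, co, inf, tol = 1e-10)
  # DG trace at the boundary edge nearest (R, 0), beam direction
  bex <- which.min(abs(((be$theta + pi) %% (2 * pi)) - pi))
  e <- be$elem[bex]; l <- be$loc[bex]
  val <- mean(f$values[3 * (e - 1) + c(l, l %% 3 + 1), 1])
  expect_equal(val, exp(-2), tolerance = 0.02)
})

test_that("the beam error decreases under simultaneous mesh/angle refinement", {
  beam_err <- function(tgt, n_dir) {
    m <- mesh_disk(10, tgt, seed = 1)
    g <- build_angular_grid(n_dir, 0)
    co <- optical_coefficients(rep(0.1, m$n_elements), rep(1e-9, m$n_elements), m)
    be <- m$boundary_edges
    inf <- inflow_constant(m, g, which(be$mid_x < 0), value = 1, dirs = 1L)
    f <- solve_rte(m, g, co, inf, tol = 1e-10)
    bex <- which.min(abs(((be$theta + pi) %% (2 * pi)) - pi))
    e <- be$elem[bex]; l <- be$loc[bex]
    abs(mean(f$values[3 * (e - 1) + c(l, l %% 3 + 1), 1]) - exp(-2))
  }
  errs <- c(beam_err(180, 8), beam_err(750, 16), beam_err(3000, 32))
  expect_true(all(diff(errs) < 0))
})

test_that("photons are conserved through a purely scattering medium", {
  tp <- tiny_problem()
  m <- tp$mesh; g <- tp$grid
  co <- optical_coefficients(rep(1e-9, m$n_elements), rep(1, m$n_elements), m)
  inf <- incident_profile(tp$units$sources[1, ], m, g)
  f <- solve_rte(m, g, co, inf, tol = 1e-12, setup = tp$setup)
  be <- m$boundary_edges
  tot_in <- 0; tot_out <- 0
  for (b in seq_len(nrow(be))) {
    s <- as.vector(g$directions %*% c(be$nx[b], be$ny[b]))
    e <- be$elem[b]; l <- be$loc[b]
    ua <- f$values[3 * (e - 1) + l, ]
    ub <- f$values[3 * (e - 1) + l %% 3 + 1, ]
    inn <- s < 0; out <- s > 0
    tot_in <- tot_in + sum(-s[inn] * g$weights[inn] *
                           (inf$moments[2 * b - 1, inn] + inf$moments[2 * b, inn]))
    tot_out <- tot_out + sum(s[out] * g$weights[out] * be$length[b] *
                             (ua[out] + ub[out]) / 2)
  }
  expect_equal(tot_out, tot_in, tolerance = 0.005)
})

test_that("detector readings integrate the outgoing angular flux correctly", {
  tp <- tiny_problem()
  det <- tp$units$detectors[1, ]
  # isotropic boundary radiance u = c  ->  reading = c * int cos = 2 c
  g32 <- build_angular_grid(32, 0)
  m <- tp$mesh
  fld <- structure(list(values = matrix(1.7, 3 * m$n_elements, 32),
                        mesh = m, grid = g32), class = "radiance_field")
  expect_equal(boundary_exitance(fld, det, g32), 2 * 1.7, tolerance = 0.01)
  # zero field -> zero reading
  fld0 <- structure(list(values = matrix(0, 3 * m$n_elements, 32),
                         mesh = m, grid = g32), class = "radiance_field")
  expect_equal(boundary_exitance(fld0, det, g32), 0)
  # single outgoing direction with omega.nu ~ 1 -> reading = w * (omega.nu)
  be <- m$boundary_edges
  nu <- c(be$nx[det$bedge], be$ny[det$bedge])
  p <- which.max(g32$directions %*% nu)
  v <- matrix(0, 3 * m$n_elements, 32)
  e <- be$elem[det$bedge]
  v[3 * (e - 1) + 1:3, p] <- 1
  fld1 <- structure(list(values = v, mesh = m, grid = g32),
                    class = "radiance_field")
  expect_equal(boundary_exitance(fld1, det, g32),
               g32$weights[p] * sum(g32$directions[p, ] * nu))
})

test_that("the forward map is linear in the source and monotone in absorption", {
  tp <- tiny_problem()
  fm <- forward_map(tp$coeffs, tp$units$sources, tp$units$detectors,
                    tp$mesh, tp$grid, tol = 1e-10, setup = tp$setup)
  expect_equal(dim(fm$M), c(3L, 3L))
  expect_true(all(fm$M > 0))
  # doubling the incident amplitude doubles every reading: solve with a
  # doubled inflow directly
  inf2 <- incident_profile(tp$units$sources[1, ], tp$mesh, tp$grid)
  inf2$moments <- 2 * inf2$moments
  f2 <- solve_rte(tp$mesh, tp$grid, tp$coeffs, inf2, tol = 1e-10, setup = tp$setup)
  r2 <- boundary_exitance(f2, tp$units$detectors[1, ], tp$grid)
  expect_equal(r2, 2 * fm$M[1, 1], tolerance = 1e-8)
  # +10% absorption strictly decreases every entry
  up <- optical_coefficients(1.1 * tp$coeffs$mua, tp$coeffs$mus, tp$mesh)
  fup <- forward_map(up, tp$units$sources, tp$units$detectors,
                     tp$mesh, tp$grid, tol = 1e-10, setup = tp$setup)
  expect_true(all(fup$M < fm$M))
})

test_that("multiplicative noise has the contracted law and determinism", {
  tp <- tiny_problem()
  fm <- forward_map(tp$coeffs, tp$units$sources, tp$units$detectors,
                    tp$mesh, tp$grid, setup = tp$setup)
  expect_identical(add_noise(fm, 0, 1)$M, fm$M)
  n1 <- add_noise(fm, 0.01, 123)
  n2 <- add_noise(fm, 0.01, 123)
  expect_identical(n1$M, n2$M)
  expect_false(identical(n1$M, add_noise(fm, 0.01, 124)$M))
  expect_equal(n1$noise$delta, 0.01)
  expect_equal(n1$noise$seed, 123L)
  # law of large numbers on one entry over many replicate draws
  draws <- vapply(seq_len(10000L),
                  function(s) add_noise(fm, 0.01, s)$M[1, 1], 0)
  expect_equal(stats::sd(draws) / abs(fm$M[1, 1]), 0.01, tolerance = 0.03)
})

test_that("measurement CSV round trip preserves readings and noise metadata", {
  tp <- tiny_problem()
  fm <- forward_map(tp$coeffs, tp$units$sources, tp$units$detectors,
                    tp$mesh, tp$grid, setup = tp$setup)
  fm <- add_noise(fm, 0.005, 99)
  f <- tempfile(fileext = ".csv")
  write_measurements_csv(fm, f, meta = list(note = "fixture"))
  back <- read_measurements_csv(f)
  expect_equal(back$M, fm$M)
  expect_equal(back$noise$delta, 0.005)
  expect_equal(back$noise$seed, 99L)
})
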
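test_that("disk meshes satisfy the structural invariants at several resolutions", {
  for (tgt in c(16L, 100L, 1484L)) {
    m <- mesh_disk(10, tgt, seed = 1)
    expect_silent(validate_mesh(m))
    expect_true(all(m$areas > 0))
    expect_lte(abs(m$n_elements - tgt) / tgt, 0.10)
    # polygonal area deficit only: below pi R^2, within a few percent
    expect_lt(sum(m$areas), pi * 100)
    expect_gt(sum(m$areas), pi * 100 * 0.90)
  }
  # the area deficit shrinks monotonically under refinement
  a <- vapply(c(100L, 400L, 1600L),
              function(t) sum(mesh_disk(10, t, seed = 1)$areas), 0)
  expect_true(all(diff(a) > 0))
  # reported node/element scale of the bundled experiments
  m <- mesh_disk(10, 2440, seed = 1)
  expect_lte(abs(nrow(m$nodes) - 1296) / 1296, 0.10)
})

test_that("meshes are deterministic in the seed and differ across seeds", {
  m1 <- mesh_disk(10, 300, seed = 7)
  m2 <- mesh_disk(10, 300, seed = 7)
  m3 <- mesh_disk(10, 300, seed = 8)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$triangles, m2$triangles)
  expect_false(isTRUE(all.equal(m1$nodes, m3$nodes)))
})

test_that("boundary unit placement snaps to edges and yields all source-detector pairs", {
  m <- medium_mesh()
  g <- build_angular_grid(32, 0.9)
  pb <- place_boundary_units(m, 12, 12, g)
  expect_equal(nrow(pb$sources), 12L)
  expect_equal(nrow(pb$detectors), 12L)
  expect_equal(nrow(pb$sources) * nrow(pb$detectors), 144L)
  # no source shares an edge with a detector (counts permit here)
  expect_length(intersect(pb$sources$bedge, pb$detectors$bedge), 0L)
  # snapped positions close to nominal: within one boundary edge length
  maxlen <- max(m$boundary_edges$length)
  nominal <- 2 * pi * (0:11) / 12
  th <- atan2(pb$sources$y, pb$sources$x) %% (2 * pi)
  gap <- abs(((th - nominal + pi) %% (2 * pi)) - pi) * m$radius
  expect_true(all(gap <= maxlen))
  # incident directions point inward: omega . nu < 0 on the source edge
  be <- m$boundary_edges
  for (i in 1:12) {
    nu <- c(be$nx[pb$sources$bedge[i]], be$ny[pb$sources$bedge[i]])
    expect_lt(sum(g$directions[pb$sources$dir_index[i], ] * nu), 0)
  }
  expect_error(place_boundary_units(mesh_disk(1, 16, seed = 1), 30, 30, g),
               "boundary edges")
})

test_that("a single source/detector pair gets a near-inward incident direction", {
  m <- medium_mesh()
  g <- build_angular_grid(32, 0.9)
  pb <- place_boundary_units(m, 1, 1, g)
  src <- pb$sources[1, ]
  inward <- -c(src$x, src$y) / sqrt(src$x^2 + src$y^2)
  ang <- acos(sum(g$directions[src$dir_index, ] * inward))
  expect_lte(ang, 2 * pi / 32)  # within one angular cell
})

test_that("upwind_order is a valid topological order for random directions", {
  m <- mesh_disk(10, 200, seed = 7)
  set.seed(42)
  for (rep in 1:5) {
    th <- stats::runif(1, 0, 2 * pi)
    dir <- c(cos(th), sin(th))
    o <- upwind_order(m, dir)
    expect_setequal(o, seq_len(m$n_elements))
    pos <- order(o)
    ed <- m$edges
    tx <- m$nodes[ed$n2, 1] - m$nodes[ed$n1, 1]
    ty <- m$nodes[ed$n2, 2] - m$nodes[ed$n1, 2]
    s <- dir[1] * ty - dir[2] * tx   # omega . n, n out of el1
    bad <- (s > 1e-12 & pos[ed$el1] > pos[ed$el2]) |
           (s < -1e-12 & pos[ed$el2] > pos[ed$el1])
    expect_equal(sum(bad), 0L)
  }
  expect_equal(length(upwind_order(m, c(1, 0))), m$n_elements)
})

test_that("piecewise-constant transfer preserves constants and inclusion areas", {
  ma <- mesh_disk(10, 800, seed = 3)
  mb <- mesh_disk(10, 300, seed = 4)
  expect_equal(transfer_piecewise_constant(rep(3.5, ma$n_elements), ma, mb),
               rep(3.5, mb$n_elements))
  # indicator of a disk: transferred area within one boundary layer
  ca <- t(vapply(seq_len(ma$n_elements),
                 function(k) colMeans(ma$nodes[ma$triangles[k, ], ]), numeric(2)))
  ind <- as.numeric((ca[, 1] - 3)^2 + ca[, 2]^2 < 4)   # r = 2 disk at (3, 0)
  vb <- transfer_piecewise_constant(ind, ma, mb)
  area_b <- sum(mb$areas[vb > 0.5])
  h <- sqrt(max(mb$areas))
  expect_lte(abs(area_b - 4 * pi), 2 * pi * 2 * 2 * h)  # perimeter * cell size
})

test_that("mesh text round trip is bit exact", {
  m <- mesh_disk(7.5, 150, seed = 9)
  base <- file.path(tempdir(), "roundtrip")
  write_mesh(m, base)
  m2 <- read_mesh(base)
  expect_identical(m2$nodes, m$nodes)
  expect_identical(m2$triangles, m$triangles)
  expect_equal(m2$areas, m$areas)
})
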
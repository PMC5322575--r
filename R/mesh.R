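#' Triangulate a disk
#'
#' Deterministic unstructured-looking triangulation of a disk of the
#' given radius, built from concentric rings of nodes joined by a
#' zipper (advancing-front) rule.  Ring node counts are scaled so the
#' element count lands within about 10% of `target_elements`; the
#' `seed` rotates each ring by a deterministic pseudo-random offset so
#' that meshes with different seeds (or different targets) are
#' genuinely different triangulations of the same disk -- used to keep
#' data-synthesis and inversion meshes distinct.
#'
#' @param radius disk radius in mm.
#' @param target_elements requested number of triangles (>= 16).
#' @param seed integer controlling the ring offsets.
#' @param boundary optional boundary-ring specification
#'   `list(m = <node count>, off = <rotation offset>)`, typically the
#'   `boundary_ring` field of another disk mesh.  Forcing two meshes to
#'   share their boundary ring makes boundary edges (hence source and
#'   detector geometry) identical while the interiors still differ --
#'   the configuration used for the dual-mesh experiments, where data
#'   synthesis and inversion must not share the interior discretization
#'   but must agree on the physical sources.
#' @return an object of class `tri_mesh`; see Details.  The field
#'   `boundary_ring` records the outer ring so other meshes can adopt
#'   it.
#' @details The returned list has fields `nodes` (V x 2, mm),
#'   `triangles` (N x 3 node indices, counterclockwise), `areas` (mm^2),
#'   `edges` (interior edges: node pair, the two adjacent triangles,
#'   length), `boundary_edges` (node pair, adjacent triangle, length,
#'   outward unit normal, midpoint angle), `n_elements`, `radius`.
#' @export
mesh_disk <- function(radius, target_elements, seed = 1L,
                      boundary = NULL) {
  if (!is.numeric(radius) || radius <= 0) stop("'radius' must be positive")
  if (target_elements < 16) stop("'target_elements' must be at least 16")

  # ring k has m_k nodes at radius k * radius / n_ring; search the ring
  # count and a scale factor so the element count (2*sum(m) - m_n: the
  # central fan has m_1 triangles, annulus k has m_{k-1} + m_k) lands on
  # the target despite integer rounding
  n0 <- max(2L, as.integer(round(sqrt(target_elements / 6 + 1))))
  best <- NULL; best_dev <- Inf
  for (n_try in unique(pmax(2L, n0 + (-1:1)))) {
    f0 <- target_elements / (6 * max(1, n_try^2 - 1))
    for (fac in seq(0.75, 1.3, by = 0.005)) {
      mm <- pmax(4L, as.integer(round(6 * f0 * fac * seq_len(n_try))))
      cnt <- 2L * sum(mm) - mm[n_try]
      dev <- abs(cnt - target_elements)
      if (dev < best_dev) { best_dev <- dev; best <- list(n = n_try, m = mm) }
    }
  }
  n_ring <- best$n
  m <- best$m
  offs_override <- NULL
  if (!is.null(boundary)) {   # adopt the prescribed outer ring
    m[n_ring] <- boundary$m
    offs_override <- boundary$off
  }
  offs <- ((seq_len(n_ring) * 0.3819660112501051 +
            (seed %% 100000L) * 0.7548776662466927) %% 1)
  if (!is.null(offs_override)) offs[n_ring] <- offs_override

  nodes <- matrix(0, nrow = 1L + sum(m), ncol = 2L)
  ring_start <- integer(n_ring)  # index of first node of ring k
  pos <- 2L
  for (k in seq_len(n_ring)) {
    ring_start[k] <- pos
    th <- 2 * pi * ((seq_len(m[k]) - 1L) + offs[k]) / m[k]
    r <- radius * k / n_ring
    nodes[pos:(pos + m[k] - 1L), ] <- cbind(r * cos(th), r * sin(th))
    pos <- pos + m[k]
  }
  # boundary ring: keep exactly on the circle, no radial perturbation
  ring_angle <- function(k) 2 * pi * ((seq_len(m[k]) - 1L) + offs[k]) / m[k]

  tris <- vector("list", n_ring)
  # central fan
  o <- ring_start[1L] + seq_len(m[1L]) - 1L
  onext <- c(o[-1L], o[1L])
  tris[[1L]] <- cbind(o, onext, 1L)
  # annuli
  for (k in 2L:n_ring) {
    if (n_ring < 2L) break
    ai <- ring_angle(k - 1L); ao <- ring_angle(k)
    ii <- ring_start[k - 1L] + seq_len(m[k - 1L]) - 1L
    oo <- ring_start[k] + seq_len(m[k]) - 1L
    tris[[k]] <- zipper_annulus(ii, ai, oo, ao)
  }
  triangles <- do.call(rbind, tris)
  dimnames(triangles) <- NULL
  storage.mode(triangles) <- "integer"

  mesh <- build_tri_mesh(nodes, triangles, radius = radius)
  dev <- abs(mesh$n_elements - target_elements) / target_elements
  if (dev > 0.10)
    stop(sprintf("mesh_disk: element count %d misses target %d by %.1f%% (radius=%g, seed=%d)",
                 mesh$n_elements, target_elements, 100 * dev, radius, seed))
  mesh$boundary_ring <- list(m = m[n_ring], off = offs[n_ring])
  mesh
}

# merge-triangulate the annulus between an inner ring (indices ii at
# angles ai) and an outer ring (oo at ao); angles ascending in [0,2pi).
zipper_annulus <- function(ii, ai, oo, ao) {
  m_in <- length(ii); m_out <- length(oo)
  # align start: begin at the outer node closest in angle to inner node 1
  j0 <- which.min(abs(((ao - ai[1L] + pi) %% (2 * pi)) - pi))
  rot <- function(x, j) if (j > 1L) c(x[j:length(x)], x[1L:(j - 1L)]) else x
  oo <- rot(oo, j0); ao2 <- rot(ao, j0)
  ao2 <- ai[1L] + ((ao2 - ai[1L]) %% (2 * pi))   # unwrap from inner start
  ai2 <- ai[1L] + ((ai - ai[1L]) %% (2 * pi))
  # closed traversal: append wrapped first nodes
  I <- c(ii, ii[1L]); A <- c(ai2, ai2[1L] + 2 * pi)
  O <- c(oo, oo[1L]); B <- c(ao2, ao2[1L] + 2 * pi)
  out <- matrix(0L, nrow = m_in + m_out, ncol = 3L)
  i <- 1L; j <- 1L; t <- 0L
  while (i <= m_in || j <= m_out) {
    adv_outer <- if (j > m_out) FALSE else if (i > m_in) TRUE else B[j + 1L] <= A[i + 1L]
    t <- t + 1L
    if (adv_outer) {
      out[t, ] <- c(O[j], O[j + 1L], I[i]); j <- j + 1L
    } else {
      out[t, ] <- c(I[i], O[j], I[i + 1L]); i <- i + 1L
    }
  }
  out[seq_len(t), , drop = FALSE]
}

#' Assemble a `tri_mesh` from raw node and triangle arrays
#'
#' Computes areas (fixing orientation to counterclockwise), the interior
#' edge table with adjacency, and the ordered boundary loop with outward
#' normals.  Used by [mesh_disk()] and [read_mesh()].
#'
#' @param nodes V x 2 numeric matrix of coordinates (mm).
#' @param triangles N x 3 integer matrix of node indices.
#' @param radius nominal disk radius, if known (NA otherwise).
#' @return a `tri_mesh` object.
#' @export
build_tri_mesh <- function(nodes, triangles, radius = NA_real_) {
  stopifnot(ncol(nodes) == 2L, ncol(triangles) == 3L)
  x1 <- nodes[triangles[, 1L], 1L]; y1 <- nodes[triangles[, 1L], 2L]
  x2 <- nodes[triangles[, 2L], 1L]; y2 <- nodes[triangles[, 2L], 2L]
  x3 <- nodes[triangles[, 3L], 1L]; y3 <- nodes[triangles[, 3L], 2L]
  signed <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  flip <- signed < 0
  if (any(flip)) {  # enforce CCW
    tmp <- triangles[flip, 2L]
    triangles[flip, 2L] <- triangles[flip, 3L]
    triangles[flip, 3L] <- tmp
  }
  areas <- abs(signed)
  if (any(areas <= 0)) stop("degenerate triangle (zero area) in mesh")
  n_el <- nrow(triangles)

  # edge table: each triangle contributes edges (1,2), (2,3), (3,1)
  ea <- c(triangles[, 1L], triangles[, 2L], triangles[, 3L])
  eb <- c(triangles[, 2L], triangles[, 3L], triangles[, 1L])
  el <- rep(seq_len(n_el), times = 3L)
  loc <- rep(1:3, each = n_el)
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  first <- match(key, key)
  dup <- first != seq_along(key)
  partner <- rep(NA_integer_, length(key))
  partner[first[dup]] <- which(dup)

  is_rep <- !dup
  interior <- is_rep & !is.na(partner)
  bnd <- is_rep & is.na(partner)

  len_all <- sqrt((nodes[ea, 1L] - nodes[eb, 1L])^2 +
                  (nodes[ea, 2L] - nodes[eb, 2L])^2)

  edges <- data.frame(
    n1 = ea[interior], n2 = eb[interior],
    el1 = el[interior], el2 = el[partner[interior]],
    loc1 = loc[interior], loc2 = loc[partner[interior]],
    length = len_all[interior]
  )

  # boundary edges, oriented as stored in their (unique) triangle, so the
  # outward normal is the right-hand perpendicular of (n1 -> n2)
  bn1 <- ea[bnd]; bn2 <- eb[bnd]
  tx <- nodes[bn2, 1L] - nodes[bn1, 1L]
  ty <- nodes[bn2, 2L] - nodes[bn1, 2L]
  blen <- len_all[bnd]
  mx <- (nodes[bn1, 1L] + nodes[bn2, 1L]) / 2
  my <- (nodes[bn1, 2L] + nodes[bn2, 2L]) / 2
  boundary_edges <- data.frame(
    n1 = bn1, n2 = bn2, elem = el[bnd], loc = loc[bnd],
    length = blen,
    nx = ty / blen, ny = -tx / blen,   # CCW triangle => right normal is outward
    mid_x = mx, mid_y = my,
    theta = atan2(my, mx) %% (2 * pi)
  )
  boundary_edges <- boundary_edges[order(boundary_edges$theta), ]
  rownames(boundary_edges) <- NULL

  structure(
    list(nodes = nodes, triangles = triangles, areas = areas,
         edges = edges, boundary_edges = boundary_edges,
         n_elements = n_el, radius = radius),
    class = "tri_mesh"
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d nodes, %d triangles, %d boundary edges, area %.4g mm^2\n",
              nrow(x$nodes), x$n_elements, nrow(x$boundary_edges), sum(x$areas)))
  invisible(x)
}

#' Check the structural invariants of a triangulation
#'
#' Asserts positive areas, the planar Euler relation
#' \eqn{V - E + F = 1} (outer face excluded), and that the boundary
#' edges form a single closed loop.  Returns the mesh invisibly so the
#' call can be chained; stops with a message on violation.
#'
#' @param mesh a `tri_mesh`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (any(mesh$areas <= 0)) stop("mesh has non-positive triangle areas")
  V <- nrow(mesh$nodes)
  E <- nrow(mesh$edges) + nrow(mesh$boundary_edges)
  F <- mesh$n_elements
  if (V - E + F != 1L)
    stop(sprintf("Euler relation violated: V - E + F = %d", V - E + F))
  be <- mesh$boundary_edges
  # closed loop: every boundary node appears exactly once as n1 and once as n2
  if (!setequal(be$n1, be$n2) || anyDuplicated(be$n1) || anyDuplicated(be$n2))
    stop("boundary edges do not form a single closed loop")
  # connectivity of the loop
  nxt <- match(be$n2, be$n1)
  seen <- logical(nrow(be)); i <- 1L
  for (s in seq_len(nrow(be))) { seen[i] <- TRUE; i <- nxt[i] }
  if (!all(seen)) stop("boundary loop is not connected")
  invisible(mesh)
}

#' Place equispaced sources and detectors on the boundary
#'
#' Sources sit at nominal angles \eqn{2\pi i/n_{src}} and detectors at
#' \eqn{2\pi (j + 1/2)/n_{det}} (interleaved so a detector never sits
#' inside a source support when counts permit), each snapped to the
#' nearest boundary edge.  A source's incident direction is the grid
#' direction closest to the inward vector from its edge midpoint toward
#' the domain centre.
#'
#' @param mesh a `tri_mesh`.
#' @param n_src,n_det numbers of sources and detectors (>= 1).
#' @param grid an `angular_grid` supplying the discrete directions.
#' @return list with `sources` and `detectors` data frames.  Sources
#'   carry `index`, `bedge` (row in `mesh$boundary_edges`), the edge
#'   midpoint `x`, `y` (the peak of the incident hat profile) and
#'   `dir_index`; detectors carry `index`, `bedge` and the position
#'   `x`, `y`.
#' @export
place_boundary_units <- function(mesh, n_src, n_det, grid) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(grid, "angular_grid"))
  if (n_src < 1 || n_det < 1) stop("need at least one source and one detector")
  be <- mesh$boundary_edges
  nb <- nrow(be)
  if (nb < n_src || nb < n_det) stop("more units than boundary edges")

  snap <- function(theta0, taken) {
    d <- abs(((be$theta - theta0 + pi) %% (2 * pi)) - pi)
    d[taken] <- Inf
    which.min(d)
  }
  taken <- logical(nb)
  src_edge <- integer(n_src)
  for (i in seq_len(n_src)) {
    src_edge[i] <- snap(2 * pi * (i - 1) / n_src, taken)
    taken[src_edge[i]] <- TRUE
  }
  det_edge <- integer(n_det)
  allow_shared <- nb < n_src + n_det
  for (j in seq_len(n_det)) {
    det_edge[j] <- snap(2 * pi * (j - 1 + 0.5) / n_det, if (allow_shared) logical(nb) else taken)
    if (!allow_shared) taken[det_edge[j]] <- TRUE
  }

  inward <- cbind(-be$mid_x[src_edge], -be$mid_y[src_edge])
  inward <- inward / sqrt(rowSums(inward^2))
  dir_index <- max.col(inward %*% t(grid$directions), ties.method = "first")

  list(
    sources = data.frame(index = seq_len(n_src), bedge = src_edge,
                         x = be$mid_x[src_edge], y = be$mid_y[src_edge],
                         dir_index = dir_index),
    detectors = data.frame(index = seq_len(n_det), bedge = det_edge,
                           x = be$mid_x[det_edge], y = be$mid_y[det_edge])
  )
}

#' Upwind sweep order of the elements for one transport direction
#'
#' Returns a permutation of element indices in which every element
#' appears after all of its upwind neighbours (neighbours whose shared
#' edge has \eqn{\omega \cdot n < 0} into the element), so a single pass
#' solves the discrete advection exactly.  Edges with
#' \eqn{|\omega \cdot n|} below `tie_tol` are treated as non-coupling;
#' should the dependency graph still contain a cycle (possible only
#' through such degeneracies), the remaining elements are ordered by the
#' projection of their centroids onto the direction.
#'
#' @param mesh a `tri_mesh`.
#' @param direction unit 2-vector.
#' @param tie_tol tolerance below which a crossing is ignored.
#' @return integer permutation of `1:n_elements`.
#' @export
upwind_order <- function(mesh, direction, tie_tol = 1e-12) {
  stopifnot(inherits(mesh, "tri_mesh"), length(direction) == 2L)
  direction <- direction / sqrt(sum(direction^2))
  ed <- mesh$edges
  n <- mesh$n_elements
  if (nrow(ed) == 0L) return(seq_len(n))
  # normal of each interior edge pointing from el1 into el2
  tx <- mesh$nodes[ed$n2, 1L] - mesh$nodes[ed$n1, 1L]
  ty <- mesh$nodes[ed$n2, 2L] - mesh$nodes[ed$n1, 2L]
  # edge (n1,n2) is stored CCW in el1, so its right-hand perpendicular
  # points out of el1 (into el2)
  nx <- ty; ny <- -tx
  s <- (direction[1L] * nx + direction[2L] * ny) / sqrt(nx^2 + ny^2)
  up <- ifelse(s > tie_tol, ed$el1, ifelse(s < -tie_tol, ed$el2, NA_integer_))
  dn <- ifelse(s > tie_tol, ed$el2, ifelse(s < -tie_tol, ed$el1, NA_integer_))
  keep <- !is.na(up)
  up <- up[keep]; dn <- dn[keep]

  indeg <- tabulate(dn, nbins = n)
  adj_order <- order(up)
  adj_start <- c(0L, cumsum(tabulate(up, nbins = n)))
  dn_sorted <- dn[adj_order]

  out <- integer(n)
  queue <- integer(n)
  roots <- which(indeg == 0L)
  queue[seq_along(roots)] <- roots
  tail <- length(roots)
  head <- 1L; cnt <- 0L
  while (head <= tail) {
    e <- queue[head]; head <- head + 1L
    cnt <- cnt + 1L; out[cnt] <- e
    if (adj_start[e + 1L] > adj_start[e]) {
      for (t in dn_sorted[(adj_start[e] + 1L):adj_start[e + 1L]]) {
        indeg[t] <- indeg[t] - 1L
        if (indeg[t] == 0L) { tail <- tail + 1L; queue[tail] <- t }
      }
    }
  }
  if (cnt < n) {  # cycle fallback: order leftovers along the direction
    left <- setdiff(seq_len(n), out[seq_len(cnt)])
    cx <- rowMeans(matrix(mesh$nodes[t(mesh$triangles[left, , drop = FALSE]), 1L], nrow = 3L))
    cy <- rowMeans(matrix(mesh$nodes[t(mesh$triangles[left, , drop = FALSE]), 2L], nrow = 3L))
    out[(cnt + 1L):n] <- left[order(cx * direction[1L] + cy * direction[2L])]
  }
  out
}

#' Transfer a piecewise-constant element field between meshes
#'
#' Each target element takes the value of the source element containing
#' its centroid.  Centroids that fall outside every source element
#' (possible in the sliver between the two polygonal boundaries) are
#' assigned from the nearest source element, with a warning.
#'
#' @param values per-element field on `mesh_a`.
#' @param mesh_a source mesh.
#' @param mesh_b target mesh.
#' @return per-element field on `mesh_b`.
#' @export
transfer_piecewise_constant <- function(values, mesh_a, mesh_b) {
  stopifnot(length(values) == mesh_a$n_elements)
  ca <- element_centroids(mesh_a)
  cb <- element_centroids(mesh_b)
  idx <- locate_points(mesh_a, cb)
  miss <- is.na(idx)
  if (any(miss)) {
    warning(sprintf("%d target centroids outside the source mesh; using nearest element", sum(miss)))
    for (i in which(miss)) {
      d2 <- (ca[, 1L] - cb[i, 1L])^2 + (ca[, 2L] - cb[i, 2L])^2
      idx[i] <- which.min(d2)
    }
  }
  values[idx]
}

#' @keywords internal
element_centroids <- function(mesh) {
  t(vapply(seq_len(mesh$n_elements), function(k) {
    colMeans(mesh$nodes[mesh$triangles[k, ], , drop = FALSE])
  }, numeric(2L)))
}

# point location via a uniform grid of buckets over the mesh bounding box
locate_points <- function(mesh, pts) {
  nd <- mesh$nodes; tr <- mesh$triangles
  xr <- range(nd[, 1L]); yr <- range(nd[, 2L])
  h <- 2 * sqrt(max(mesh$areas))
  nxc <- max(1L, ceiling(diff(xr) / h)); nyc <- max(1L, ceiling(diff(yr) / h))
  cell_of <- function(x, y) {
    cx <- pmin(nxc, pmax(1L, 1L + floor((x - xr[1L]) / diff(xr) * nxc)))
    cy <- pmin(nyc, pmax(1L, 1L + floor((y - yr[1L]) / diff(yr) * nyc)))
    (cy - 1L) * nxc + cx
  }
  buckets <- vector("list", nxc * nyc)
  for (k in seq_len(nrow(tr))) {
    px <- nd[tr[k, ], 1L]; py <- nd[tr[k, ], 2L]
    cxs <- unique(cell_of(c(min(px), max(px), min(px), max(px)),
                          c(min(py), min(py), max(py), max(py))))
    # cover the whole bbox cell range
    c1 <- cell_of(min(px), min(py)); c2 <- cell_of(max(px), max(py))
    ix1 <- (c1 - 1L) %% nxc + 1L; iy1 <- (c1 - 1L) %/% nxc + 1L
    ix2 <- (c2 - 1L) %% nxc + 1L; iy2 <- (c2 - 1L) %/% nxc + 1L
    for (iy in iy1:iy2) for (ix in ix1:ix2) {
      cc <- (iy - 1L) * nxc + ix
      buckets[[cc]] <- c(buckets[[cc]], k)
    }
  }
  out <- rep(NA_integer_, nrow(pts))
  tol <- -1e-12
  for (i in seq_len(nrow(pts))) {
    for (k in buckets[[cell_of(pts[i, 1L], pts[i, 2L])]]) {
      a <- nd[tr[k, 1L], ]; b <- nd[tr[k, 2L], ]; cc <- nd[tr[k, 3L], ]
      det <- (b[1L] - a[1L]) * (cc[2L] - a[2L]) - (cc[1L] - a[1L]) * (b[2L] - a[2L])
      l2 <- ((pts[i, 1L] - a[1L]) * (cc[2L] - a[2L]) - (cc[1L] - a[1L]) * (pts[i, 2L] - a[2L])) / det
      l3 <- ((b[1L] - a[1L]) * (pts[i, 2L] - a[2L]) - (pts[i, 1L] - a[1L]) * (b[2L] - a[2L])) / det
      if (l2 >= tol && l3 >= tol && 1 - l2 - l3 >= tol) { out[i] <- k; break }
    }
  }
  out
}

#' Write / read a mesh in Triangle-style `.node`/`.ele` text files
#'
#' The `.node` file holds `V 2 0 0` then one `index x y` record per
#' node; the `.ele` file holds `N 3 0` then `index n1 n2 n3`.  Indices
#' are 1-based (stated in the header comment).  Coordinates are printed
#' with 17 significant digits so a write/read cycle is bit-exact.
#'
#' @param mesh a `tri_mesh`.
#' @param basename path without extension; `.node` and `.ele` are added.
#' @return `write_mesh` returns `basename` invisibly; `read_mesh`
#'   returns a `tri_mesh`.
#' @export
write_mesh <- function(mesh, basename) {
  nf <- paste0(basename, ".node"); ef <- paste0(basename, ".ele")
  nd <- mesh$nodes
  con <- file(nf, "w")
  writeLines(c("# rtetomo mesh nodes (1-based indices)",
               sprintf("%d 2 0 0", nrow(nd)),
               sprintf("%d %.17g %.17g", seq_len(nrow(nd)), nd[, 1L], nd[, 2L])), con)
  close(con)
  tr <- mesh$triangles
  con <- file(ef, "w")
  writeLines(c("# rtetomo mesh elements (1-based indices)",
               sprintf("%d 3 0", nrow(tr)),
               sprintf("%d %d %d %d", seq_len(nrow(tr)), tr[, 1L], tr[, 2L], tr[, 3L])), con)
  close(con)
  invisible(basename)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(basename) {
  nf <- paste0(basename, ".node"); ef <- paste0(basename, ".ele")
  nl <- grep("^\\s*#", readLines(nf), value = TRUE, invert = TRUE)
  hd <- scan(text = nl[1L], quiet = TRUE)
  nv <- as.integer(hd[1L])
  rec <- scan(text = nl[-1L], quiet = TRUE)
  rec <- matrix(rec, ncol = 3L, byrow = TRUE)
  nodes <- rec[order(rec[, 1L]), 2:3, drop = FALSE]
  stopifnot(nrow(nodes) == nv)
  el <- grep("^\\s*#", readLines(ef), value = TRUE, invert = TRUE)
  hd <- scan(text = el[1L], quiet = TRUE)
  ne <- as.integer(hd[1L])
  rec <- scan(text = el[-1L], quiet = TRUE)
  rec <- matrix(as.integer(rec), ncol = 4L, byrow = TRUE)
  tris <- rec[order(rec[, 1L]), 2:4, drop = FALSE]
  stopifnot(nrow(tris) == ne)
  r <- max(sqrt(rowSums(nodes^2)))
  build_tri_mesh(nodes, tris, radius = r)
}
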
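#' Solve the adjoint transport problem for one detector
#'
#' The sensitivity of a detector reading to the absorption coefficient
#' involves the adjoint radiance, which satisfies the reverse-transport
#' equation.  By the reciprocity of the Boltzmann kernel the adjoint
#' can be computed with the *forward* solver: solve the forward-form
#' equation with inflow trace equal to the detector weight on the
#' detector edge (constant \eqn{1/|e_j|}, matching the edge-averaged
#' reading convention of [boundary_exitance()]) and recover the adjoint
#' by reversing every direction, \eqn{\varphi(x, \omega) =
#' \hat\varphi(x, -\omega)}.
#'
#' The direction reversal is exact on the equispaced grid when `n_dir`
#' is even (direction `p` maps to `p + n_dir/2` modulo `n_dir`).
#'
#' @inheritParams solve_rte
#' @param det one row of the `detectors` frame (field `bedge`).
#' @return a `radiance_field` holding \eqn{\hat\varphi}; apply
#'   [reverse_directions()] to obtain \eqn{\varphi}.
#' @export
solve_adjoint <- function(mesh, grid, coeffs, det, tol = 1e-8,
                          max_iter = 2000L, method = "gmres",
                          setup = NULL, init = NULL, dsa = NULL) {
  if (grid$n_dir %% 2L != 0L)
    stop("adjoint direction reversal requires an even number of directions")
  b <- det$bedge
  len <- mesh$boundary_edges$length[b]
  inflow <- inflow_constant(mesh, grid, b, value = 1 / len)
  solve_rte(mesh, grid, coeffs, inflow, tol = tol, max_iter = max_iter,
            method = method, setup = setup, init = init, dsa = dsa)
}

#' Reverse all directions of a radiance field
#'
#' Maps direction index `p` to its antipode `p + n_dir/2` (mod
#' `n_dir`); used to turn the forward-solved \eqn{\hat\varphi} into the
#' adjoint radiance \eqn{\varphi}.
#'
#' @param field a `radiance_field` on an even-`n_dir` grid.
#' @export
reverse_directions <- function(field) {
  n_dir <- ncol(field$values)
  if (n_dir %% 2L != 0L) stop("direction reversal requires even n_dir")
  perm <- (seq_len(n_dir) - 1L + n_dir %/% 2L) %% n_dir + 1L
  field$values <- field$values[, perm, drop = FALSE]
  field
}

#' Jacobian block of one source with respect to per-element absorption
#'
#' Entry `(j, k)` is \eqn{\partial M_{j,i} / \partial \mu_{a,k} =
#' -\int_{K_k} \int_\Omega u_i \varphi_j \, d\sigma(\omega)\, dx}
#' (increasing absorption can only decrease transmitted light, so all
#' entries are nonpositive up to quadrature noise).  The spatial
#' integral uses the exact product quadrature of the two linear DG
#' fields; the angular integral uses the grid weights.
#'
#' @param u_i solved forward `radiance_field` for source `i`.
#' @param adjoints list of adjoint fields \eqn{\hat\varphi_j} as
#'   returned by [solve_adjoint()] (directions not yet reversed), one
#'   per detector.
#' @param mesh,grid discretization (must match the fields).
#' @return a `d x N` matrix.
#' @export
jacobian_block <- function(u_i, adjoints, mesh, grid) {
  if (!identical(dim(u_i$values), dim(adjoints[[1L]]$values)))
    stop("forward and adjoint fields live on different discretizations")
  if (nrow(u_i$values) != 3L * mesh$n_elements)
    stop("fields do not match the mesh")
  J <- matrix(0, length(adjoints), mesh$n_elements)
  for (j in seq_along(adjoints)) {
    phi <- reverse_directions(adjoints[[j]])
    J[j, ] <- -cpp_field_product(u_i$values, phi$values,
                                 mesh$areas, grid$weights)
  }
  J
}

#' Full absorption Jacobian by the adjoint method
#'
#' Computes every source's Jacobian block from `s` forward solves and
#' only `d` adjoint solves: the adjoint fields depend on the detector,
#' not on the source, so they are shared across all blocks.  (The
#' direct alternative would cost one forward solve per element per
#' source-detector pair.)
#'
#' @inheritParams forward_map
#' @param fields optional list of already-solved forward fields (e.g.
#'   from `forward_map(..., keep_fields = TRUE)`); missing entries are
#'   solved here.
#' @param adjoint_init optional list of adjoint fields used as warm
#'   starts.
#' @return list with `blocks` (list of d x N matrices, one per
#'   source), `fields`, `adjoints` and `n_adjoint_solves`.
#' @export
full_jacobian <- function(coeffs, sources, detectors, mesh, grid,
                          tol = 1e-8, max_iter = 2000L, method = "gmres",
                          setup = NULL, fields = NULL,
                          adjoint_init = NULL) {
  if (is.null(setup)) setup <- dg_setup(mesh, grid)
  s <- nrow(sources); d <- nrow(detectors)
  dsa <- if (identical(method, "gmres")) build_dsa(setup, coeffs) else NULL
  if (is.null(fields)) fields <- vector("list", s)
  for (i in seq_len(s)) {
    if (is.null(fields[[i]])) {
      inflow <- incident_profile(sources[i, ], mesh, grid)
      fields[[i]] <- solve_rte(mesh, grid, coeffs, inflow, tol = tol,
                               max_iter = max_iter, method = method,
                               setup = setup, dsa = dsa)
    }
  }
  adjoints <- vector("list", d)
  for (j in seq_len(d)) {
    adjoints[[j]] <- solve_adjoint(mesh, grid, coeffs, detectors[j, ],
                                   tol = tol, max_iter = max_iter,
                                   method = method, setup = setup,
                                   init = adjoint_init[[j]], dsa = dsa)
  }
  blocks <- lapply(fields, jacobian_block, adjoints = adjoints,
                   mesh = mesh, grid = grid)
  list(blocks = blocks, fields = fields, adjoints = adjoints,
       n_adjoint_solves = d)
}
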
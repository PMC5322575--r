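#' Assemble the fully coupled discrete transport system
#'
#' Builds the global sparse matrix and right-hand side of the upwind DG
#' discretization with the scattering coupling included, over all
#' elements, nodes and directions at once.  The degree of freedom for
#' local node `i` of element `k` in direction `p` has index
#' `((p-1) N + (k-1)) * 3 + i`, so the matrix is the direction-block
#' transport operator minus the scattering coupling
#' \eqn{S \otimes \mathrm{blockdiag}_k(\mu_{s,k} M_k)}.
#'
#' Solving this system directly is exact up to sparse-LU roundoff and
#' serves both as the reference for the iterative transport drivers and
#' as a fast multi-right-hand-side driver: one factorization of the
#' system can be reused for every source and adjoint solve sharing the
#' same coefficients (see [rte_factor()]).
#'
#' @inheritParams solve_rte
#' @param inflow an `rte_inflow`, or `NULL` to assemble the matrix only.
#' @return list with sparse `A` (`dgCMatrix`) and dense `b` (`NULL` if
#'   `inflow` is `NULL`).
#' @export
assemble_rte_system <- function(mesh, grid, coeffs, inflow = NULL,
                                setup = NULL) {
  if (is.null(setup)) setup <- dg_setup(mesh, grid)
  N <- mesh$n_elements
  n_dir <- grid$n_dir
  n3 <- 3L * N

  # element-local index helpers (within one direction block)
  eidx <- function(k, i) (k - 1L) * 3L + i   # k, i vectors

  Mpat <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3L) / 12
  rows9 <- as.vector(matrix(rep(1:3, 3L), 3L))        # 1 2 3 1 2 3 1 2 3
  cols9 <- rep(1:3, each = 3L)

  ks <- rep(seq_len(N), each = 9L)
  ri <- eidx(ks, rep(rows9, N))
  ci <- eidx(ks, rep(cols9, N))

  # attenuation mass blocks: (mua + mus) * area * Mpat
  sig <- (coeffs$mua + coeffs$mus) * setup$area
  v_mass <- rep(sig, each = 9L) * rep(as.vector(Mpat), N)
  # convection blocks: C[i, j] = -(omega . grad_i) * area / 3, per direction
  garea <- setup$area / 3

  # per-direction transport blocks
  blocks <- vector("list", n_dir)
  ed_packs <- edge_pack(setup)
  for (p in seq_len(n_dir)) {
    om <- grid$directions[p, ]
    gdot <- setup$grad[, c(1L, 3L, 5L)] * om[1L] + setup$grad[, c(2L, 4L, 6L)] * om[2L]
    # C is constant along columns: value depends on the test row i only
    v_conv <- -rep(garea, each = 9L) * gdot[cbind(ks, rep(rows9, N))]
    ep <- ed_packs
    s <- om[1L] * ep$nx + om[2L] * ep$ny       # omega . n for each (elem, side)
    fac <- s * ep$len / 6
    out <- s > 1e-12
    inn <- s < -1e-12 & ep$interior
    # outflow: own 2x2 edge-mass block
    ro <- c(eidx(ep$el[out], ep$a[out]), eidx(ep$el[out], ep$a[out]),
            eidx(ep$el[out], ep$b[out]), eidx(ep$el[out], ep$b[out]))
    co_ <- c(eidx(ep$el[out], ep$a[out]), eidx(ep$el[out], ep$b[out]),
             eidx(ep$el[out], ep$a[out]), eidx(ep$el[out], ep$b[out]))
    vo <- c(2 * fac[out], fac[out], fac[out], 2 * fac[out])
    # interior inflow: coupling to the neighbour's trace (negative fac)
    rn <- c(eidx(ep$el[inn], ep$a[inn]), eidx(ep$el[inn], ep$a[inn]),
            eidx(ep$el[inn], ep$b[inn]), eidx(ep$el[inn], ep$b[inn]))
    cn <- c(eidx(ep$nb[inn], ep$nla[inn]), eidx(ep$nb[inn], ep$nlb[inn]),
            eidx(ep$nb[inn], ep$nla[inn]), eidx(ep$nb[inn], ep$nlb[inn]))
    vn <- c(2 * fac[inn], fac[inn], fac[inn], 2 * fac[inn])
    blocks[[p]] <- Matrix::sparseMatrix(
      i = c(ri, ro, rn), j = c(ci, co_, cn),
      x = c(v_mass + v_conv, vo, vn), dims = c(n3, n3))
  }
  A_tr <- Matrix::bdiag(blocks)

  # scattering: S (directions) kron blockdiag(mus_k * area_k * Mpat)
  v_sc <- rep(coeffs$mus * setup$area, each = 9L) * rep(as.vector(Mpat), N)
  BD <- Matrix::sparseMatrix(i = ri, j = ci, x = v_sc, dims = c(n3, n3))
  A <- A_tr - Matrix::kronecker(methods::as(grid$scatter_matrix, "sparseMatrix"), BD)

  b <- NULL
  if (!is.null(inflow)) b <- assemble_rhs(setup, inflow)
  list(A = methods::as(A, "CsparseMatrix"), b = b)
}

# flatten the per-element side tables of a dg_setup
edge_pack <- function(setup) {
  N <- nrow(setup$tri)
  el <- rep(seq_len(N), 3L)
  side <- rep(1:3, each = N)
  list(el = el, a = side, b = side %% 3L + 1L,
       nx = as.vector(setup$nnx), ny = as.vector(setup$nny),
       len = as.vector(setup$elen),
       nb = as.vector(setup$nb_el), nla = as.vector(setup$nb_la),
       nlb = as.vector(setup$nb_lb),
       bid = as.vector(setup$bid),
       interior = as.vector(setup$nb_el) > 0L)
}

# global right-hand side from boundary inflow moments
assemble_rhs <- function(setup, inflow) {
  grid <- setup$grid
  N <- nrow(setup$tri); n3 <- 3L * N
  be <- setup$mesh$boundary_edges
  b <- numeric(n3 * grid$n_dir)
  s_all <- outer(be$nx, grid$directions[, 1L]) + outer(be$ny, grid$directions[, 2L])
  for (p in seq_len(grid$n_dir)) {
    s <- s_all[, p]
    act <- which(s < -1e-12)
    if (!length(act)) next
    off <- (p - 1L) * n3
    ia <- off + (be$elem[act] - 1L) * 3L + be$loc[act]
    ib <- off + (be$elem[act] - 1L) * 3L + be$loc[act] %% 3L + 1L
    b[ia] <- b[ia] - s[act] * inflow$moments[2L * act - 1L, p]
    b[ib] <- b[ib] - s[act] * inflow$moments[2L * act, p]
  }
  b
}

#' Direct sparse solve of the fully coupled transport system
#'
#' Reference solver: assembles the global system via
#' [assemble_rte_system()] and solves it with a sparse LU
#' factorization.  Returns a `radiance_field` shaped like the output of
#' [solve_rte()].
#'
#' @inheritParams solve_rte
#' @export
solve_rte_direct <- function(mesh, grid, coeffs, inflow, setup = NULL) {
  if (is.null(setup)) setup <- dg_setup(mesh, grid)
  fac <- rte_factor(mesh, grid, coeffs, setup = setup)
  rte_solve_factored(fac, inflow)
}

#' Factorize the coupled transport operator for repeated solves
#'
#' Computes a sparse LU factorization of the fully coupled system of
#' [assemble_rte_system()].  The factorization depends only on the
#' coefficients (not on the inflow), so one factorization serves every
#' source and every adjoint solve at the current coefficient iterate --
#' the work pattern of the reconstruction loop, where measurements and
#' the Jacobian are re-evaluated once per outer iteration.
#'
#' @inheritParams solve_rte
#' @return an `rte_factor` object for [rte_solve_factored()].
#' @export
rte_factor <- function(mesh, grid, coeffs, setup = NULL) {
  if (is.null(setup)) setup <- dg_setup(mesh, grid)
  sys <- assemble_rte_system(mesh, grid, coeffs, inflow = NULL, setup = setup)
  structure(list(lu = Matrix::lu(sys$A), setup = setup,
                 mesh = mesh, grid = grid),
            class = "rte_factor")
}

#' @rdname rte_factor
#' @param fac an `rte_factor`.
#' @export
rte_solve_factored <- function(fac, inflow) {
  stopifnot(inherits(fac, "rte_factor"))
  b <- assemble_rhs(fac$setup, inflow)
  x <- as.vector(Matrix::solve(fac$lu, b))
  N <- fac$mesh$n_elements
  u <- matrix(x, 3L * N, fac$grid$n_dir)
  structure(list(values = u, mesh = fac$mesh, grid = fac$grid,
                 iterations = 1L, residual = 0, method = "direct"),
            class = "radiance_field")
}
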
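#' Regularization and iteration parameters for the reconstruction
#'
#' @param alpha total-variation weight (>= 0).
#' @param beta L1 weight (>= 0).
#' @param eta split (augmented-coupling) parameter (>= 0); it also acts
#'   as the Levenberg-Marquardt damping of the linear step.  `eta = 0`
#'   with `beta > 0` is invalid (the shrinkage threshold would be
#'   undefined).
#' @param eps smoothing constant of the total-variation functional
#'   (> 0); keeps the lagged-diffusivity weights finite at zero jumps.
#' @param max_outer cap on outer (Bregman/LM) iterations.
#' @param stop_tol relative iterate-change stopping threshold.
#' @param box lower/upper projection bounds for the absorption
#'   coefficient, mm^-1 (keeps every iterate inside the admissible set
#'   of uniformly positive bounded coefficients).
#' @param solver_tol,solver_max_iter transport solver controls used
#'   inside the reconstruction.
#' @param scaling how the data misfit is normalized so the
#'   regularization weights are dimensionless fractions of the data
#'   curvature.  `"absolute"` (default) fits raw readings, with
#'   residuals and Jacobians divided by the square root of the peak
#'   diagonal of the Gauss-Newton Hessian at the initial iterate
#'   (frozen thereafter); `"relative"` additionally divides residual
#'   entries by the measured magnitudes before the curvature
#'   normalization (equalizes near and far source-detector pairs, the
#'   natural choice under strongly varying dynamic range); `"none"`
#'   applies no normalization at all.
#' @param lm_damping Levenberg-Marquardt trust-region damping: a
#'   multiple of the peak data curvature added as \eqn{\lambda I} to
#'   the linear system, penalizing the step size around the current
#'   iterate without biasing its direction.  Keeps the linear step
#'   well-scaled even when the penalty terms are weak (notably the
#'   pure-L1 variant, whose only other damping is the small
#'   \eqn{\eta}); 0 disables.
#' @return a list of class `reg_params`.
#' @export
reg_params <- function(alpha, beta, eta, eps = 1e-6, max_outer = 100L,
                       stop_tol = 1e-4, box = c(1e-4, 1),
                       solver_tol = 1e-8, solver_max_iter = 2000L,
                       scaling = c("absolute", "relative", "none"),
                       lm_damping = 0.1) {
  if (lm_damping < 0) stop("'lm_damping' must be nonnegative")
  scaling <- match.arg(scaling)
  if (alpha < 0 || beta < 0 || eta < 0) stop("alpha, beta, eta must be nonnegative")
  if (eps <= 0) stop("eps must be positive")
  if (beta > 0 && eta == 0) stop("beta > 0 requires eta > 0 (shrinkage threshold beta/eta)")
  if (box[1L] <= 0 || box[2L] <= box[1L]) stop("invalid projection box")
  structure(list(alpha = alpha, beta = beta, eta = eta, eps = eps,
                 max_outer = as.integer(max_outer), stop_tol = stop_tol,
                 box = box, solver_tol = solver_tol,
                 solver_max_iter = as.integer(solver_max_iter),
                 scaling = scaling, lm_damping = lm_damping),
            class = "reg_params")
}

#' Smoothed total variation of a piecewise-constant element field
#'
#' For a piecewise-constant field the total variation is the
#' perimeter-weighted sum of inter-element jumps; the smoothed version
#' replaces each |jump| by \eqn{\sqrt{jump^2 + \epsilon^2}}:
#' \deqn{TV_\epsilon(\mu) = \sum_{e} |e| \sqrt{(\mu_{e^+} - \mu_{e^-})^2
#'   + \epsilon^2}.}
#' A constant field therefore evaluates to `eps` times the total
#' interior edge length.
#'
#' @param mu per-element field.
#' @param mesh a `tri_mesh`.
#' @param eps smoothing constant (> 0; `0` is accepted and gives the
#'   exact seminorm).
#' @return scalar.
#' @export
tv_smoothed <- function(mu, mesh, eps) {
  ed <- mesh$edges
  jump <- mu[ed$el1] - mu[ed$el2]
  sum(ed$length * sqrt(jump^2 + eps^2))
}

#' Lagged-diffusivity linearization of the smoothed TV term
#'
#' Assembles the symmetric positive-semidefinite matrix `L` with
#' edgewise weights \eqn{w_e = |e| / \sqrt{jump_e(\mu^n)^2 +
#' \epsilon^2}} (off-diagonals \eqn{-w_e}, diagonals accumulating
#' \eqn{+w_e}): an edge-length-weighted graph Laplacian on the element
#' adjacency graph, frozen at the current iterate.  Its quadratic form
#' \eqn{\langle L\mu, \mu\rangle} is the Gateaux linearization of the
#' smoothed TV functional, and `L %*% rep(1, N)` is exactly zero.
#'
#' @param mu_n per-element field at which the weights are frozen.
#' @inheritParams tv_smoothed
#' @return sparse symmetric `N x N` matrix (`dgCMatrix`).
#' @export
tv_operator <- function(mu_n, mesh, eps) {
  if (eps <= 0) stop("eps must be positive")
  ed <- mesh$edges
  w <- ed$length / sqrt((mu_n[ed$el1] - mu_n[ed$el2])^2 + eps^2)
  N <- mesh$n_elements
  Matrix::sparseMatrix(
    i = c(ed$el1, ed$el2, ed$el1, ed$el2),
    j = c(ed$el2, ed$el1, ed$el1, ed$el2),
    x = c(-w, -w, w, w),
    dims = c(N, N))
}

#' Soft-thresholding (shrinkage) operator
#'
#' Componentwise \eqn{shrink(x, t) = sign(x)\max(|x| - t, 0)}: the
#' closed-form minimizer of \eqn{t\|d\|_1 + \frac12\|d - x\|^2}.
#'
#' @param x numeric vector (or scalar).
#' @param t threshold, >= 0.
#' @export
shrink <- function(x, t) {
  if (t < 0) stop("shrinkage threshold must be nonnegative")
  sign(x) * pmax(abs(x) - t, 0)
}

#' Levenberg-Marquardt linear step of the TV-L1 objective
#'
#' Solves the normal equations of the quadratic model around the
#' current iterate \eqn{\mu^n} (data terms linearized with the adjoint
#' Jacobian, smoothed TV replaced by its lagged-diffusivity quadratic
#' form, split/L1 coupling through the `eta` term):
#' \deqn{\Big(\sum_i J_i^T J_i + \alpha L(\mu^n) + \eta I\Big)\,\delta =
#'  -\sum_i J_i^T r_i - \alpha L(\mu^n)\,\mu^n + \eta\,(D^n - \mu^n - b^n)}
#' and returns \eqn{\mu^n + \delta} (before box projection).  The
#' system matrix is symmetric positive definite whenever `eta > 0`, or
#' when `alpha > 0` and the Jacobian sees the constant vector.
#'
#' @param mua_n current per-element absorption iterate.
#' @param jacobians list of `d x N` Jacobian blocks at `mua_n`.
#' @param residuals `d x s` matrix of residuals `F_i(mua_n) - M_i`
#'   (column i = source i).
#' @param D_n,b_n splitting and Bregman variables (per element).
#' @param mesh a `tri_mesh`.
#' @param params a [reg_params()].
#' @param damping extra Levenberg-Marquardt damping \eqn{\lambda}: a
#'   multiple of the peak Gauss-Newton curvature added to the diagonal
#'   (no gradient contribution, so it shortens the step without
#'   changing the stationary point of the outer iteration).
#' @return per-element updated field (unprojected).
#' @export
lm_step <- function(mua_n, jacobians, residuals, D_n, b_n, mesh, params,
                    damping = 0) {
  N <- length(mua_n)
  Jall <- do.call(rbind, jacobians)            # s blocks of d rows
  rall <- as.vector(residuals)                 # column-major: same order
  H <- crossprod(Jall)
  g <- -as.vector(crossprod(Jall, rall))
  if (damping > 0)
    H <- H + damping * max(diag(H)) * diag(N)
  if (params$alpha > 0) {
    L <- tv_operator(mua_n, mesh, params$eps)
    H <- H + params$alpha * L
    g <- g - params$alpha * as.vector(L %*% mua_n)
  }
  if (params$eta > 0) {
    Matrix::diag(H) <- Matrix::diag(H) + params$eta
    g <- g + params$eta * (D_n - mua_n - b_n)
  }
  H <- as.matrix(H)
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    if (params$eta == 0 && params$alpha == 0)
      stop("singular LM system: all regularizers are zero and J'J is rank deficient; set eta > 0")
    delta <- solve(H, g)
  } else {
    delta <- backsolve(ch, forwardsolve(t(ch), g))
  }
  # the step must not increase the quadratic model (0 at delta = 0)
  qmod <- -sum(g * delta) + 0.5 * sum(delta * (H %*% delta))
  if (qmod > 1e-10 * max(1, abs(sum(g * delta))))
    warning("LM step failed to decrease its quadratic model")
  mua_n + as.vector(delta)
}

#' Relative residual and solution errors
#'
#' \deqn{E_{resi} = \frac{\|F(\mu_a^n) - F(\mu_a^{true})\|_2}
#'   {\|F(\mu_a^{true})\|_2}, \qquad
#'   E_{\mu_a} = \frac{\|\mu_a^n - \mu_a^{true}\|_2}{\|\mu_a^{true}\|_2}}
#' with plain (unweighted) Euclidean norms of the stacked measurement
#' entries and of the element coefficient vectors.
#'
#' @param mua_n,mua_true per-element fields on the same mesh.
#' @param F_n,F_true measurement matrices (or vectors) for the two
#'   fields.
#' @return list with `E_resi` and `E_mua`.
#' @export
error_metrics <- function(mua_n, mua_true, F_n, F_true) {
  if (length(mua_n) != length(mua_true)) stop("coefficient vectors differ in length")
  den_m <- sqrt(sum(mua_true^2))
  den_f <- sqrt(sum(F_true^2))
  if (den_m == 0 || den_f == 0) stop("zero denominator in error metric")
  list(E_resi = sqrt(sum((F_n - F_true)^2)) / den_f,
       E_mua = sqrt(sum((mua_n - mua_true)^2)) / den_m)
}

#' One outer iteration of the split Bregman TV-L1 reconstruction
#'
#' Performs: (i) forward map and residuals at the current iterate,
#' (ii) adjoint Jacobian, (iii) the LM linear step, (iv) projection
#' onto the box, (v) the shrinkage update of the splitting variable
#' \eqn{D^{n+1} = shrink(\mu_a^{n+1} + b^n, \beta/\eta)} (skipped --
#' identity -- when `beta = 0` and `eta = 0`), (vi) the Bregman update
#' \eqn{b^{n+1} = b^n + \mu_a^{n+1} - D^{n+1}}.
#'
#' @param state a `recon_state` (see [reconstruct()]).
#' @param data `measurement_set` with the measured matrix `M`.
#' @param problem list with `mesh`, `grid`, `sources`, `detectors`,
#'   `mus` (known per-element scattering), `setup`, and optionally
#'   `truth` (per-element true absorption on the inverse mesh) plus
#'   `F_true` for error tracking.
#' @param params a [reg_params()].
#' @return updated `recon_state`.
#' @export
bregman_iterate <- function(state, data, problem, params) {
  mesh <- problem$mesh; grid <- problem$grid
  co <- optical_coefficients(state$mua_n, problem$mus, mesh)
  fm <- forward_map(co, problem$sources, problem$detectors, mesh, grid,
                    tol = params$solver_tol, max_iter = params$solver_max_iter,
                    setup = problem$setup, keep_fields = TRUE,
                    init_fields = state$fields)
  resid <- fm$M - data$M
  fj <- full_jacobian(co, problem$sources, problem$detectors, mesh, grid,
                      tol = params$solver_tol,
                      max_iter = params$solver_max_iter,
                      setup = problem$setup, fields = fm$fields,
                      adjoint_init = state$adjoints)
  blocks <- fj$blocks
  gamma <- state$gamma
  if (params$scaling %in% c("relative", "absolute")) {
    if (identical(params$scaling, "relative")) {
      S <- pmax(abs(data$M), 1e-8 * max(abs(data$M)))
      resid <- resid / S
      blocks <- lapply(seq_along(blocks), function(i) blocks[[i]] / S[, i])
    }
    if (is.null(gamma)) {
      # peak diagonal of the (scaled) Gauss-Newton Hessian, frozen at
      # the first iterate so the objective is fixed across iterations
      gamma <- max(Reduce(`+`, lapply(blocks, function(J) colSums(J^2))))
    }
    resid <- resid / sqrt(gamma)
    blocks <- lapply(blocks, function(J) J / sqrt(gamma))
  }
  mua_new <- lm_step(state$mua_n, blocks, resid, state$D_n, state$b_n,
                     mesh, params, damping = params$lm_damping)
  mua_new <- pmin(pmax(mua_new, params$box[1L]), params$box[2L])
  if (params$beta > 0 || params$eta > 0) {
    thr <- if (params$eta > 0) params$beta / params$eta else 0
    D_new <- shrink(mua_new + state$b_n, thr)
  } else {
    D_new <- mua_new + state$b_n     # threshold-0 shrinkage: identity
  }
  b_new <- state$b_n + mua_new - D_new

  obj_data <- 0.5 * sum(resid^2)   # in scaled units when scaling is on
  hist_row <- data.frame(
    iter = state$iter + 1L,
    E_resi = if (!is.null(problem$F_true))
      sqrt(sum((fm$M - problem$F_true)^2)) / sqrt(sum(problem$F_true^2)) else NA_real_,
    E_mua = if (!is.null(problem$truth))
      sqrt(sum((state$mua_n - problem$truth)^2)) / sqrt(sum(problem$truth^2)) else NA_real_,
    data_fidelity = obj_data,
    tv = tv_smoothed(state$mua_n, mesh, params$eps),
    l1 = sum(abs(state$mua_n)),
    step = sqrt(sum((mua_new - state$mua_n)^2)) / sqrt(sum(state$mua_n^2)))

  structure(list(mua_n = mua_new, D_n = D_new, b_n = b_new,
                 iter = state$iter + 1L,
                 history = rbind(state$history, hist_row),
                 fields = fm$fields, adjoints = fj$adjoints,
                 gamma = gamma),
            class = "recon_state")
}

#' Split Bregman TV-L1 reconstruction of the absorption coefficient
#'
#' Runs [bregman_iterate()] from the background initialization until
#' the relative iterate change drops below `params$stop_tol`, the
#' data-fidelity objective increases five times in a row (divergence
#' guard; returns with a warning), or `params$max_outer` is reached.
#' The scattering coefficient is assumed known and fixed.
#'
#' @param data `measurement_set` holding the measured `M`.
#' @param mesh inverse-problem mesh.
#' @param grid angular grid.
#' @param mus known per-element scattering coefficient on `mesh`.
#' @param init_mua initial per-element absorption (typically the
#'   background value).
#' @param params a [reg_params()].
#' @param sources,detectors unit placement on `mesh` (defaults to the
#'   placement stored in `data`, which is only valid when data and
#'   inversion share the mesh; with a dual-mesh setup pass the inverse
#'   mesh's own placement).
#' @param truth optional true per-element absorption on `mesh`; when
#'   given, `E_mua` (and `E_resi` against `F_true`, if supplied) are
#'   tracked per iteration.
#' @param F_true optional noise-free measurement matrix of the truth.
#' @return list with `mua` (final field), `state` (full `recon_state`
#'   with history), `converged`, `iterations`.
#' @export
reconstruct <- function(data, mesh, grid, mus, init_mua, params,
                        sources = data$sources, detectors = data$detectors,
                        truth = NULL, F_true = NULL) {
  if (any(init_mua < params$box[1L] - 1e-15) || any(init_mua > params$box[2L] + 1e-15))
    stop("initial absorption outside the projection box")
  setup <- dg_setup(mesh, grid)
  problem <- list(mesh = mesh, grid = grid, sources = sources,
                  detectors = detectors, mus = mus, setup = setup,
                  truth = truth, F_true = F_true)
  state <- structure(list(mua_n = init_mua, D_n = init_mua,
                          b_n = rep(0, length(init_mua)), iter = 0L,
                          history = NULL, fields = NULL, adjoints = NULL,
                          gamma = NULL),
                     class = "recon_state")
  converged <- FALSE
  bad_streak <- 0L
  for (n in seq_len(params$max_outer)) {
    state <- bregman_iterate(state, data, problem, params)
    h <- state$history
    if (n >= 2L) {
      bad_streak <- if (h$data_fidelity[n] > 1.01 * h$data_fidelity[n - 1L])
        bad_streak + 1L else 0L
      if (bad_streak >= 5L) {
        warning("objective increased 5 consecutive iterations; stopping")
        break
      }
    }
    if (h$step[n] < params$stop_tol) { converged <- TRUE; break }
  }
  list(mua = state$mua_n, state = state, converged = converged,
       iterations = state$iter)
}

#' @export
print.recon_state <- function(x, ...) {
  cat(sprintf("<recon_state> iteration %d, mua in [%.4g, %.4g]\n",
              x$iter, min(x$mua_n), max(x$mua_n)))
  invisible(x)
}
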
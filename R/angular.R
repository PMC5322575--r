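#' Discrete direction set on the unit circle
#'
#' Builds an equispaced set of `n_dir` angular collocation points on
#' \eqn{[0, 2\pi)} with midpoint-rule quadrature weights \eqn{2\pi/n}.
#' The direction set carries the discrete scattering operator once
#' [build_scatter_matrix()] has been called; by default the matrix is
#' filled with the isotropic kernel (`g = 0`).
#'
#' Angles are measured from the positive x-axis, counterclockwise.
#'
#' @param n_dir number of directions (at least 4).
#' @param g anisotropy factor used to fill the scattering matrix;
#'   defaults to 0 (isotropic).
#' @return an object of class `angular_grid` with fields `n_dir`,
#'   `angles`, `directions` (`n_dir` x 2 matrix of unit vectors),
#'   `weights` (summing to \eqn{2\pi}), `scatter_matrix` and `g`.
#' @examples
#' grid <- build_angular_grid(32)
#' sum(grid$weights)  # 2*pi
#' @export
build_angular_grid <- function(n_dir, g = 0) {
  if (!is.numeric(n_dir) || length(n_dir) != 1L || n_dir != round(n_dir) || n_dir < 4)
    stop("'n_dir' must be a single integer >= 4")
  n_dir <- as.integer(n_dir)
  angles <- 2 * pi * (seq_len(n_dir) - 1L) / n_dir
  grid <- structure(
    list(
      n_dir = n_dir,
      angles = angles,
      directions = cbind(cos(angles), sin(angles)),
      weights = rep(2 * pi / n_dir, n_dir),
      scatter_matrix = NULL,
      g = NA_real_
    ),
    class = "angular_grid"
  )
  build_scatter_matrix(grid, g)
}

#' Two-dimensional Henyey-Greenstein phase function
#'
#' Evaluates the 2D Henyey-Greenstein scattering density
#' \deqn{k(c) = \frac{1 - g^2}{2\pi\,(1 + g^2 - 2 g c)},}
#' where `c` is the cosine of the scattering angle.  The density is
#' normalized over the unit circle: \eqn{\int_0^{2\pi} k(\cos\theta)\,
#' d\theta = 1}.
#'
#' @param g anisotropy factor, strictly inside (-1, 1).  `g > 0` is
#'   forward-peaked scattering, `g = 0` isotropic.
#' @param c cosine(s) of the scattering angle, in \eqn{[-1, 1]}.
#' @return density value(s), per radian.
#' @examples
#' hg_phase(0, 0.3)        # 1/(2*pi)
#' hg_phase(0.9, 1)        # forward peak
#' @export
hg_phase <- function(g, c) {
  if (!is.numeric(g) || length(g) != 1L || abs(g) >= 1)
    stop("anisotropy 'g' must satisfy |g| < 1")
  if (any(abs(c) > 1 + 1e-12))
    stop("cosine 'c' must lie in [-1, 1]")
  (1 - g^2) / (2 * pi * (1 + g^2 - 2 * g * c))
}

#' Fill the discrete scattering operator of an angular grid
#'
#' Assembles the `n_dir` x `n_dir` matrix whose action on a radiance
#' vector over directions approximates the scattering integral
#' \eqn{\int_\Omega k(\omega\cdot\hat\omega) u(\hat\omega)\,
#' d\sigma(\hat\omega)} by the grid quadrature:
#' `S[p, q] = k(omega_p . omega_q) * w_q`.  Each row is then rescaled to
#' sum exactly to 1 so that the discrete kernel conserves photons (the
#' continuous kernel is normalized; without the repair, quadrature error
#' breaks the conservation balance).  For equispaced angles the matrix
#' is circulant.
#'
#' @param grid an `angular_grid`.
#' @param g anisotropy factor, |g| < 1.
#' @return the grid with `scatter_matrix` and `g` filled.
#' @export
build_scatter_matrix <- function(grid, g) {
  stopifnot(inherits(grid, "angular_grid"))
  cosdiff <- cos(outer(grid$angles, grid$angles, "-"))
  cosdiff[cosdiff > 1] <- 1
  cosdiff[cosdiff < -1] <- -1
  S <- hg_phase(g, cosdiff) * rep(grid$weights, each = grid$n_dir)
  S <- S / rowSums(S)
  grid$scatter_matrix <- S
  grid$g <- g
  grid
}

#' @export
print.angular_grid <- function(x, ...) {
  cat(sprintf("<angular_grid> %d equispaced directions, g = %.3g\n",
              x$n_dir, x$g))
  invisible(x)
}
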
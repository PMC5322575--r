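#' Piecewise-constant optical phantom
#'
#' A phantom is a homogeneous background plus circular inclusions, each
#' overriding the background absorption and/or scattering coefficient.
#' Later inclusions override earlier ones where they overlap.
#'
#' @param background_mua,background_mus background coefficients, mm^-1
#'   (both strictly positive).
#' @param inclusions list of inclusions, each a list with `center`
#'   (2-vector, mm), `radius` (mm) and optionally `mua`, `mus` (mm^-1;
#'   an omitted coefficient keeps the background value inside the
#'   circle).
#' @param domain_radius radius of the disk the phantom lives in, mm;
#'   every inclusion must fit inside it.
#' @return an object of class `phantom`.
#' @examples
#' ph <- phantom(0.01, 10, list(list(center = c(7, 0), radius = 0.5,
#'                                   mua = 0.02, mus = 20)))
#' @export
phantom <- function(background_mua, background_mus, inclusions = list(),
                    domain_radius = 10) {
  if (background_mua <= 0 || background_mus <= 0)
    stop("background coefficients must be strictly positive")
  for (inc in inclusions) {
    if (is.null(inc$center) || is.null(inc$radius))
      stop("each inclusion needs 'center' and 'radius'")
    if (inc$radius <= 0) stop("inclusion radius must be positive")
    if (sqrt(sum(inc$center^2)) + inc$radius > domain_radius + 1e-9)
      stop(sprintf("inclusion at (%g, %g) with radius %g extends outside the disk of radius %g",
                   inc$center[1L], inc$center[2L], inc$radius, domain_radius))
    mua <- if (is.null(inc$mua)) background_mua else inc$mua
    mus <- if (is.null(inc$mus)) background_mus else inc$mus
    if (mua <= 0 || mus <= 0) stop("inclusion coefficients must be strictly positive")
  }
  if (length(inclusions) > 1L) {
    ctr <- t(vapply(inclusions, function(i) as.numeric(i$center), numeric(2L)))
    rad <- vapply(inclusions, function(i) i$radius, numeric(1L))
    for (a in seq_len(length(inclusions) - 1L))
      for (b in (a + 1L):length(inclusions))
        if (sqrt(sum((ctr[a, ] - ctr[b, ])^2)) < rad[a] + rad[b])
          warning(sprintf("inclusions %d and %d overlap; the later one wins", a, b))
  }
  structure(list(background_mua = background_mua,
                 background_mus = background_mus,
                 inclusions = inclusions,
                 domain_radius = domain_radius),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> background mua=%g mus=%g mm^-1, %d inclusion(s)\n",
              x$background_mua, x$background_mus, length(x$inclusions)))
  for (inc in x$inclusions)
    cat(sprintf("  circle r=%g at (%g, %g)%s%s\n", inc$radius,
                inc$center[1L], inc$center[2L],
                if (!is.null(inc$mua)) sprintf(" mua=%g", inc$mua) else "",
                if (!is.null(inc$mus)) sprintf(" mus=%g", inc$mus) else ""))
  invisible(x)
}

#' Rasterize a phantom onto a mesh
#'
#' Element membership is decided by the element centroid: an element
#' takes an inclusion's coefficients iff its centroid lies strictly
#' inside the inclusion circle.  This keeps the true coefficient field
#' exactly representable in the piecewise-constant element basis.
#'
#' @param ph a `phantom`.
#' @param mesh a `tri_mesh`.
#' @return an `optical_coefficients` object: list with per-element
#'   vectors `mua`, `mus` (mm^-1) and the `mesh`.
#' @export
rasterize <- function(ph, mesh) {
  stopifnot(inherits(ph, "phantom"), inherits(mesh, "tri_mesh"))
  ctr <- element_centroids(mesh)
  mua <- rep(ph$background_mua, mesh$n_elements)
  mus <- rep(ph$background_mus, mesh$n_elements)
  for (inc in ph$inclusions) {
    inside <- (ctr[, 1L] - inc$center[1L])^2 + (ctr[, 2L] - inc$center[2L])^2 <
      inc$radius^2
    if (!is.null(inc$mua)) mua[inside] <- inc$mua
    if (!is.null(inc$mus)) mus[inside] <- inc$mus
  }
  optical_coefficients(mua, mus, mesh)
}

#' Per-element optical coefficients
#'
#' @param mua,mus per-element coefficient vectors, mm^-1.
#' @param mesh the `tri_mesh` the values live on.
#' @export
optical_coefficients <- function(mua, mus, mesh) {
  stopifnot(length(mua) == mesh$n_elements, length(mus) == mesh$n_elements)
  if (any(mua <= 0) || any(mus <= 0))
    stop("optical coefficients must be strictly positive everywhere")
  structure(list(mua = mua, mus = mus, mesh = mesh),
            class = "optical_coefficients")
}

#' @export
print.optical_coefficients <- function(x, ...) {
  cat(sprintf("<optical_coefficients> %d elements, mua in [%.4g, %.4g], mus in [%.4g, %.4g] mm^-1\n",
              length(x$mua), min(x$mua), max(x$mua), min(x$mus), max(x$mus)))
  invisible(x)
}

#' Preset simulation phantoms
#'
#' The named phantoms used by the bundled simulation experiments: disk
#' of radius 10 mm; Simulations 1-2 use background
#' \eqn{\mu_a = 0.01}, \eqn{\mu_s = 10} mm^-1 with inclusions at
#' \eqn{\mu_a = 0.02}, \eqn{\mu_s = 20}; Simulation 3 uses background
#' (0.05, 5) with one purely absorbing and one purely scattering
#' inclusion.
#'
#' @param name one of `"sim1_small"`, `"sim2_small"`, `"sim2_middle"`,
#'   `"sim2_big"`, `"sim2_two_small"`, `"sim2_three_small"`,
#'   `"sim2_big_two_small"`, `"sim3_abs_scat"`.
#' @return a `phantom`.
#' @export
preset_phantom <- function(name) {
  inc <- function(cx, cy, r, mua = NULL, mus = NULL) {
    out <- list(center = c(cx, cy), radius = r)
    if (!is.null(mua)) out$mua <- mua
    if (!is.null(mus)) out$mus <- mus
    out
  }
  std <- function(...) phantom(0.01, 10, list(...))
  switch(name,
    sim1_small = ,
    sim2_small = std(inc(7, 0, 0.5, 0.02, 20)),
    sim2_middle = std(inc(5, 0, 2, 0.02, 20)),
    sim2_big = std(inc(3, 0, 4, 0.02, 20)),
    sim2_two_small = std(inc(7, 0, 0.5, 0.02, 20),
                         inc(0, 0, 0.5, 0.02, 20)),
    sim2_three_small = std(inc(7, 0, 0.5, 0.02, 20),
                           inc(0, -7, 0.5, 0.02, 20),
                           inc(0, 0, 0.5, 0.02, 20)),
    sim2_big_two_small = std(inc(-5, 2, 2, 0.02, 20),
                             inc(0, -7, 0.5, 0.02, 20),
                             inc(7, 0, 0.5, 0.02, 20)),
    sim3_abs_scat = phantom(0.05, 5, list(inc(3.5, 3.5, 2, mua = 0.1),
                                          inc(0, -5, 2, mus = 10))),
    stop(sprintf("unknown phantom '%s'; valid names: %s", name,
                 paste(c("sim1_small", "sim2_small", "sim2_middle", "sim2_big",
                         "sim2_two_small", "sim2_three_small",
                         "sim2_big_two_small", "sim3_abs_scat"),
                       collapse = ", ")))
  )
}

#' Export per-element coefficient fields as CSV
#'
#' Columns `element_index` (1-based), `mua`, `mus`.
#'
#' @param coeffs an `optical_coefficients`.
#' @param path output file.
#' @export
write_coefficients_csv <- function(coeffs, path) {
  utils::write.csv(data.frame(element_index = seq_along(coeffs$mua),
                              mua = coeffs$mua, mus = coeffs$mus),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
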
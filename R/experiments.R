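#' Configuration of a simulation experiment
#'
#' Bundles everything needed for an end-to-end run: phantom, the two
#' mesh resolutions (data are synthesized on a finer mesh than the one
#' used for inversion, so the inversion never sees its own
#' discretization -- the classic guard against the "inverse crime"),
#' angular resolution, unit counts, regularization parameters, noise
#' and seeds.
#'
#' @param phantom a [phantom()] or a preset name for
#'   [preset_phantom()].
#' @param forward_elements,inverse_elements target element counts of
#'   the data-synthesis and inversion meshes; the forward mesh must be
#'   strictly finer.
#' @param n_dir number of transport directions (even).
#' @param g scattering anisotropy factor.
#' @param n_src,n_det numbers of sources and detectors.
#' @param params a [reg_params()].
#' @param delta multiplicative noise level (0 = exact data).
#' @param seed integer; seeds the mesh generation and the noise draw.
#' @param radius domain radius, mm.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(phantom, forward_elements, inverse_elements,
                              n_dir = 32L, g = 0.9, n_src = 12L, n_det = 12L,
                              params = reg_params(1e-4, 1e-3, 1e-5),
                              delta = 0, seed = 1L, radius = 10) {
  if (is.character(phantom)) phantom <- preset_phantom(phantom)
  if (forward_elements <= inverse_elements)
    stop("the forward (data) mesh must be finer than the inverse mesh (inverse-crime guard)")
  if (n_dir %% 2L != 0L) stop("n_dir must be even (adjoint direction reversal)")
  if (delta < 0) stop("noise level must be nonnegative")
  structure(list(phantom = phantom,
                 forward_elements = as.integer(forward_elements),
                 inverse_elements = as.integer(inverse_elements),
                 n_dir = as.integer(n_dir), g = g,
                 n_src = as.integer(n_src), n_det = as.integer(n_det),
                 params = params, delta = delta, seed = as.integer(seed),
                 radius = radius),
            class = "experiment_config")
}

#' Preset experiment configurations
#'
#' One configuration per bundled simulation case, with the phantom,
#' regularization parameters and mesh element counts of the study
#' setup (data mesh finer than the inversion mesh, 32 directions,
#' g = 0.9, 12 x 12 source-detector pairs).  Pass `scale` < 1 to run a
#' proportionally coarsened version (element counts scaled, direction
#' count halved below 0.75) -- the reconstruction problem is the same,
#' at reduced cost.
#'
#' @param name preset name; one of `"sim1_small"`, `"sim2_small"`,
#'   `"sim2_middle"`, `"sim2_big"`, `"sim2_two_small"`,
#'   `"sim2_three_small"`, `"sim2_big_two_small"`, `"sim3_abs_scat"`.
#' @param scale resolution scale factor in (0, 1].
#' @param delta,seed noise level and seed overrides.
#' @param ... further overrides passed to [experiment_config()]
#'   (e.g. `params`).
#' @export
preset_experiment <- function(name, scale = 1, delta = 0, seed = 1L, ...) {
  base <- switch(name,
    sim1_small = ,
    sim2_small = list(fe = 2440L, ie = 1484L, p = reg_params(1e-4, 1e-3, 1e-5)),
    sim2_middle = list(fe = 2642L, ie = 1080L, p = reg_params(3e-3, 3e-3, 3e-4)),
    sim2_big = list(fe = 3124L, ie = 1096L, p = reg_params(3e-3, 3e-4, 3e-4)),
    sim2_two_small = list(fe = 3616L, ie = 2488L, p = reg_params(1e-4, 1e-3, 1e-5)),
    sim2_three_small = list(fe = 4176L, ie = 3264L, p = reg_params(1e-4, 1e-3, 1e-5)),
    sim2_big_two_small = list(fe = 3512L, ie = 2568L, p = reg_params(1e-3, 1e-3, 1e-5)),
    sim3_abs_scat = list(fe = 1288L, ie = 856L, p = reg_params(5e-4, 5e-4, 1e-6)),
    stop(sprintf("unknown experiment preset '%s'", name)))
  if (scale <= 0 || scale > 1) stop("'scale' must be in (0, 1]")
  n_dir <- if (scale < 0.75) 16L else 32L
  dots <- list(...)
  args <- list(phantom = preset_phantom(name),
               forward_elements = max(48L, as.integer(round(base$fe * scale))),
               inverse_elements = max(32L, as.integer(round(base$ie * scale))),
               n_dir = n_dir, g = 0.9, n_src = 12L, n_det = 12L,
               params = base$p, delta = delta, seed = seed)
  args[names(dots)] <- dots
  do.call(experiment_config, args)
}

#' Run one experiment end to end
#'
#' Synthesizes measurements from the phantom on the forward mesh, adds
#' noise if requested, reconstructs the absorption coefficient on the
#' (coarser) inverse mesh with the known scattering map, transfers the
#' truth for the error metrics, and returns everything in a result
#' bundle.  Deterministic for a fixed configuration.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress.
#' @param metrics `"full"` evaluates both quality metrics, which costs
#'   two extra forward maps on the inverse mesh for the residual error;
#'   `"mua"` reports only the coefficient error (`E_resi` is `NA`).
#' @return list with `mua` (reconstructed field on the inverse mesh),
#'   `truth` (true absorption transferred to the inverse mesh),
#'   `E_mua`, `E_resi`, `iterations`, `history`, `meshes` (actual
#'   counts), `data`, `config`, and `summary` (flat named vector).
#' @export
run_experiment <- function(config, verbose = FALSE,
                           metrics = c("full", "mua")) {
  metrics <- match.arg(metrics)
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("experiment stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE))
  }
  grid <- build_angular_grid(config$n_dir, config$g)

  say("meshing (forward %d / inverse %d target elements)",
      config$forward_elements, config$inverse_elements)
  mesh_f <- stage("forward mesh",
                  mesh_disk(config$radius, config$forward_elements,
                            seed = config$seed))
  # the inverse mesh adopts the forward mesh's boundary ring: sources
  # and detectors are then the same physical objects on both meshes
  # (no spurious per-source amplitude mismatch), while the interior
  # triangulations differ -- the inverse-crime guard concerns the
  # interior discretization
  mesh_i <- stage("inverse mesh",
                  mesh_disk(config$radius, config$inverse_elements,
                            seed = config$seed + 1L,
                            boundary = mesh_f$boundary_ring))
  stopifnot(mesh_f$n_elements > mesh_i$n_elements)  # inverse-crime guard

  co_f <- stage("phantom", rasterize(config$phantom, mesh_f))
  co_i <- stage("phantom", rasterize(config$phantom, mesh_i))

  pb_f <- place_boundary_units(mesh_f, config$n_src, config$n_det, grid)
  pb_i <- place_boundary_units(mesh_i, config$n_src, config$n_det, grid)

  say("synthesizing data on %d elements", mesh_f$n_elements)
  data <- stage("forward data",
                forward_map(co_f, pb_f$sources, pb_f$detectors, mesh_f, grid,
                            tol = config$params$solver_tol,
                            max_iter = config$params$solver_max_iter))
  if (config$delta > 0)
    data <- add_noise(data, config$delta, config$seed + 2L)

  init <- rep(config$phantom$background_mua, mesh_i$n_elements)
  truth_i <- co_i$mua

  say("reconstructing on %d elements", mesh_i$n_elements)
  res <- stage("reconstruction",
               reconstruct(data, mesh_i, grid, co_i$mus, init, config$params,
                           sources = pb_i$sources, detectors = pb_i$detectors,
                           truth = truth_i))

  say("evaluating metrics")
  if (metrics == "full") {
    co_rec <- optical_coefficients(res$mua, co_i$mus, mesh_i)
    F_rec <- forward_map(co_rec, pb_i$sources, pb_i$detectors, mesh_i, grid,
                         tol = config$params$solver_tol,
                         max_iter = config$params$solver_max_iter,
                         init_fields = res$state$fields)$M
    F_true <- forward_map(co_i, pb_i$sources, pb_i$detectors, mesh_i, grid,
                          tol = config$params$solver_tol,
                          max_iter = config$params$solver_max_iter)$M
    em <- error_metrics(res$mua, truth_i, F_rec, F_true)
  } else {
    em <- list(E_resi = NA_real_,
               E_mua = error_metrics(res$mua, truth_i, 1, 1)$E_mua)
  }

  summary <- c(E_mua = em$E_mua, E_resi = em$E_resi,
               iterations = res$iterations,
               forward_nodes = nrow(mesh_f$nodes),
               forward_elements = mesh_f$n_elements,
               inverse_nodes = nrow(mesh_i$nodes),
               inverse_elements = mesh_i$n_elements,
               n_dir = config$n_dir, g = config$g,
               alpha = config$params$alpha, beta = config$params$beta,
               eta = config$params$eta, eps = config$params$eps,
               delta = config$delta, seed = config$seed)
  list(mua = res$mua, truth = truth_i, E_mua = em$E_mua, E_resi = em$E_resi,
       iterations = res$iterations, history = res$state$history,
       meshes = list(forward = mesh_f, inverse = mesh_i),
       data = data, config = config, summary = summary)
}

#' Run a regularization variant of an experiment
#'
#' The three regularization modes compared in the bundled simulations
#' share the same data and meshes; they differ only in which penalty
#' terms are active:
#' * `"tvl1"`: the full mixed penalty (parameters as configured);
#' * `"tv"`: pure total variation -- `beta = 0`, `eta = 0` (plain
#'   LM-TV iteration, shrinkage and Bregman steps degenerate to
#'   identities);
#' * `"l1"`: pure L1 -- `alpha = 0`.
#'
#' @param config an [experiment_config()].
#' @param variant `"tvl1"`, `"tv"` or `"l1"`.
#' @param ... passed to [run_experiment()].
#' @export
run_regularization_variant <- function(config, variant = c("tvl1", "tv", "l1"),
                                       ...) {
  variant <- match.arg(variant)
  p <- config$params
  config$params <- switch(variant,
    tvl1 = p,
    tv = reg_params(p$alpha, 0, 0, eps = p$eps, max_outer = p$max_outer,
                    stop_tol = p$stop_tol, box = p$box,
                    solver_tol = p$solver_tol,
                    solver_max_iter = p$solver_max_iter, scaling = p$scaling,
                    lm_damping = p$lm_damping),
    l1 = reg_params(0, p$beta, p$eta, eps = p$eps, max_outer = p$max_outer,
                    stop_tol = p$stop_tol, box = p$box,
                    solver_tol = p$solver_tol,
                    solver_max_iter = p$solver_max_iter, scaling = p$scaling,
                    lm_damping = p$lm_damping))
  out <- run_experiment(config, ...)
  out$variant <- variant
  out
}

#' Write an experiment summary as flat key-value text
#'
#' @param result a bundle from [run_experiment()].
#' @param path output file; the iteration history goes to
#'   `<path>.history.csv`.
#' @export
write_experiment_summary <- function(result, path) {
  s <- result$summary
  writeLines(sprintf("%s = %.10g", names(s), s), path)
  if (!is.null(result$history))
    utils::write.csv(result$history, paste0(path, ".history.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
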
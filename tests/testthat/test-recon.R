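test_that("shrinkage reproduces its branch table and algebraic properties", {
  expect_equal(shrink(0.5, 0.2), 0.3)
  expect_equal(shrink(0.1, 0.2), 0)
  expect_equal(shrink(-0.5, 0.2), -0.3)
  expect_equal(shrink(0.2, 0.2), 0)
  expect_error(shrink(1, -0.1), "nonnegative")
  set.seed(8)
  x <- stats::rnorm(50)
  expect_equal(shrink(shrink(x, 0.3), 0), shrink(x, 0.3))
  expect_equal(shrink(-x, 0.3), -shrink(x, 0.3))       # odd
  expect_true(all(abs(shrink(x, 0.3)) <= abs(x)))      # nonexpansive
})

test_that("smoothed TV matches the edge-jump form", {
  m <- mesh_disk(5, 60, seed = 2)
  tot_len <- sum(m$edges$length)
  # constant field: eps times total interior edge length
  expect_equal(tv_smoothed(rep(0.7, m$n_elements), m, 1e-3), 1e-3 * tot_len)
  # eps -> 0 recovers the exact seminorm; difference bounded termwise
  set.seed(3)
  mu <- stats::runif(m$n_elements)
  expect_lte(tv_smoothed(mu, m, 1e-6) - tv_smoothed(mu, m, 0),
             1e-6 * tot_len + 1e-12)
  # hand-computed two-element check via a one-edge submesh
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  m2 <- build_tri_mesh(nodes, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  expect_equal(nrow(m2$edges), 1L)
  expect_equal(m2$edges$length, sqrt(2))
  expect_equal(tv_smoothed(c(0, 1), m2, 0), sqrt(2))
})

test_that("the lagged-diffusivity operator is a PSD Laplacian consistent with TV", {
  m <- mesh_disk(5, 60, seed = 2)
  N <- m$n_elements
  set.seed(5)
  mu <- 0.01 + 0.01 * stats::runif(N)
  L <- tv_operator(mu, m, 1e-4)
  expect_equal(max(abs(L - Matrix::t(L))), 0)
  expect_lt(max(abs(L %*% rep(1, N))), 1e-10)
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-10)
  ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # constant linearization point: (1/eps) x edge-weighted graph Laplacian
  Lc <- tv_operator(rep(0.3, N), m, 1e-2)
  ed <- m$edges
  expect_equal(Lc[cbind(ed$el1, ed$el2)], -ed$length / 1e-2)

  # <L(mu) mu, v> equals the directional derivative of tv_smoothed at mu
  eps <- 1e-3
  L2 <- tv_operator(mu, m, eps)
  set.seed(6)
  v <- stats::rnorm(N)
  h <- 1e-7
  fd <- (tv_smoothed(mu + h * v, m, eps) - tv_smoothed(mu - h * v, m, eps)) / (2 * h)
  expect_equal(as.numeric(t(v) %*% (L2 %*% mu)), fd, tolerance = 1e-5)
})

test_that("the LM step solves its quadratic model exactly", {
  m <- mesh_disk(5, 60, seed = 2)
  N <- m$n_elements
  # stationary point: zero residuals, consistent split variables
  set.seed(7)
  mu0 <- 0.01 + 0.005 * stats::runif(N)
  J <- list(matrix(stats::rnorm(4 * N), 4, N))
  p0 <- reg_params(0, 0, 1e-3, eps = 1e-6)
  out <- lm_step(mu0, J, matrix(0, 4, 1), D_n = mu0, b_n = rep(0, N), m, p0)
  expect_equal(out, mu0, tolerance = 1e-12)

  # identity-Jacobian toy: exact Newton lands on the target
  target <- mu0 + 0.3
  Jid <- list(diag(N))
  res <- matrix(mu0 - target, N, 1)
  p1 <- reg_params(0, 0, 0, eps = 1e-6)
  out <- lm_step(mu0, Jid, res, D_n = mu0, b_n = rep(0, N), m, p1)
  expect_equal(out, target, tolerance = 1e-10)

  # general case vs a quadratic-programming oracle (BFGS on the model)
  mS <- mesh_disk(2, 16, seed = 3)
  Ns <- mS$n_elements
  set.seed(9)
  muS <- 0.02 + 0.01 * stats::runif(Ns)
  JS <- list(matrix(stats::rnorm(3 * Ns), 3, Ns),
             matrix(stats::rnorm(3 * Ns), 3, Ns))
  rS <- matrix(stats::rnorm(6) * 0.01, 3, 2)
  DS <- muS + 0.001; bS <- stats::rnorm(Ns) * 0.001
  pS <- reg_params(0.05, 0.02, 0.5, eps = 1e-3)
  LS <- tv_operator(muS, mS, pS$eps)
  objective <- function(mu) {
    d <- mu - muS
    0.5 * sum((JS[[1]] %*% d + rS[, 1])^2) +
      0.5 * sum((JS[[2]] %*% d + rS[, 2])^2) +
      0.5 * pS$alpha * as.numeric(t(mu) %*% (LS %*% mu)) +
      0.5 * pS$eta * sum((DS - mu - bS)^2)
  }
  out <- lm_step(muS, JS, rS, DS, bS, mS, pS)
  opt <- stats::optim(muS, objective, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(out, opt$par, tolerance = 1e-5)
  expect_lte(objective(out), opt$value + 1e-12)

  # degenerate singular system errors out with advice
  p_none <- reg_params(0, 0, 0, eps = 1e-6)
  Jdef <- list(matrix(0, 2, Ns))
  expect_error(lm_step(muS, Jdef, matrix(0, 2, 1), DS, bS, mS, p_none),
               "eta")
})

test_that("error metrics are homogeneous and match brute-force norms", {
  expect_equal(error_metrics(c(1, 2), c(1, 2), 5, 5)$E_mua, 0)
  expect_equal(error_metrics(1.1 * c(1, 2), c(1, 2), 5, 5)$E_mua, 0.1)
  set.seed(10)
  a <- stats::rnorm(20); b <- stats::rnorm(20)
  Fa <- stats::rnorm(12); Fb <- stats::rnorm(12)
  em <- error_metrics(a, b, Fa, Fb)
  expect_equal(em$E_mua, norm(a - b, "2") / norm(b, "2"))
  expect_equal(em$E_resi, norm(Fa - Fb, "2") / norm(Fb, "2"))
  expect_error(error_metrics(a, rep(0, 20), Fa, Fb), "denominator")
})

test_that("reg_params validates its domain", {
  expect_error(reg_params(-1, 0, 0), "nonnegative")
  expect_error(reg_params(0, 1e-3, 0), "eta")
  expect_error(reg_params(1e-4, 1e-3, 1e-5, eps = 0), "eps")
  expect_error(reg_params(1e-4, 1e-3, 1e-5, box = c(0, 1)), "box")
  p <- reg_params(1e-4, 1e-3, 1e-5)
  expect_s3_class(p, "reg_params")
  expect_equal(p$scaling, "absolute")
})

test_that("the Bregman variable update follows b + mua - D", {
  # arithmetic check decoupled from the solver: D = 0.3, mua = 0.5,
  # b = 0.1 -> b_new = 0.3, via one shrinkage round trip
  mua <- 0.5; b <- 0.1
  D <- shrink(mua + b, 0.3)   # = 0.3
  expect_equal(D, 0.3)
  expect_equal(b + mua - D, 0.3)
})

test_that("zero-contrast data are reproduced immediately from the background start", {
  tp <- tiny_problem()
  m <- tp$mesh; g <- tp$grid
  mus <- rep(2, m$n_elements)
  truth <- rep(0.05, m$n_elements)
  co <- optical_coefficients(truth, mus, m)
  un <- place_boundary_units(m, 4, 4, g)
  data <- forward_map(co, un$sources, un$detectors, m, g, tol = 1e-10,
                      setup = tp$setup)
  params <- reg_params(1e-4, 1e-3, 1e-5, max_outer = 5, stop_tol = 1e-4,
                       solver_tol = 1e-10)
  res <- reconstruct(data, m, g, mus, truth, params,
                     sources = un$sources, detectors = un$detectors)
  expect_lte(res$iterations, 2L)
  expect_true(res$converged)
  expect_equal(res$mua, truth, tolerance = 1e-3)
})

test_that("white-box recovery improves on the background initialization", {
  m <- mesh_disk(10, 250, seed = 5)
  g <- build_angular_grid(16, 0.9)
  ph <- preset_phantom("sim3_abs_scat")
  co <- rasterize(ph, m)
  un <- place_boundary_units(m, 4, 4, g)
  su <- dg_setup(m, g)
  data <- forward_map(co, un$sources, un$detectors, m, g, tol = 1e-8,
                      setup = su)
  init <- rep(ph$background_mua, m$n_elements)
  e0 <- error_metrics(init, co$mua, 1, 1)$E_mua
  params <- reg_params(5e-4, 5e-4, 1e-6, max_outer = 6, stop_tol = 1e-4,
                       solver_tol = 1e-6)
  res <- reconstruct(data, m, g, co$mus, init, params,
                     sources = un$sources, detectors = un$detectors,
                     truth = co$mua, F_true = data$M)
  ef <- error_metrics(res$mua, co$mua, 1, 1)$E_mua
  expect_lt(ef, e0)
  # E_mua decreases monotonically over the early iterations
  h <- res$state$history$E_mua
  expect_true(all(diff(h[seq_len(min(5, length(h)))]) <= 1e-10))
})

test_that("bregman degenerate parameters reduce to the pure LM-TV iteration", {
  tp <- tiny_problem()
  m <- tp$mesh; g <- tp$grid
  mus <- rep(2, m$n_elements)
  truth <- rep(0.05, m$n_elements)
  truth[10] <- 0.08
  co <- optical_coefficients(truth, mus, m)
  un <- place_boundary_units(m, 4, 4, g)
  data <- forward_map(co, un$sources, un$detectors, m, g, tol = 1e-10,
                      setup = tp$setup)
  init <- rep(0.05, m$n_elements)
  p_tv <- reg_params(1e-4, 0, 0, max_outer = 3, stop_tol = 0, solver_tol = 1e-9)
  r1 <- reconstruct(data, m, g, mus, init, p_tv,
                    sources = un$sources, detectors = un$detectors)
  r2 <- reconstruct(data, m, g, mus, init, p_tv,
                    sources = un$sources, detectors = un$detectors)
  expect_identical(r1$mua, r2$mua)    # determinism
  expect_false(isTRUE(all.equal(r1$mua, init)))
})
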
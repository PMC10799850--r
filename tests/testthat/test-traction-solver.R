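test_that("the TV proximal map matches the exact 1D denoiser", {
  set.seed(21)
  x <- matrix(rnorm(60), 10, 6)
  expect_identical(tv_prox(x, 0), x)
  const <- matrix(4, 12, 9)
  expect_equal(tv_prox(const, 0.7, 200L), const, tolerance = 1e-10)

  # replicated-column signals reduce isotropic 2D TV to independent 1D TV
  step <- c(rep(0, 20), rep(1, 20)) + ritfm:::with_seed(31, rnorm(40, 0, 0.15))
  Y <- matrix(rep(step, 8), 40, 8)
  ours <- tv_prox(Y, 0.3, 2000L)[, 4]
  exact <- tv1d_exact(step, 0.3)
  expect_equal(ours, exact, tolerance = 1e-8)
  # step preserved, noise variance reduced
  expect_gt(mean(exact[21:40]) - mean(exact[1:20]), 0.5)
  expect_lt(sd(exact - c(rep(mean(exact[1:20]), 20),
                         rep(mean(exact[21:40]), 20))), sd(step - rep(c(0, 1), each = 20)))

  # 3D path agrees with the exact denoiser in the same replicated geometry
  Y3 <- array(rep(step, 6 * 4), c(40, 6, 4))
  ours3 <- tv_prox(Y3, 0.3, 2000L)[, 3, 2]
  expect_equal(ours3, exact, tolerance = 1e-7)
})

test_that("FISTA solves identity and dense quadratic problems to oracle accuracy", {
  set.seed(22)
  data <- array(rnorm(64), c(8, 8))
  idop <- function(x) x
  sol <- fista_solve(idop, idop, data, fista_config(1, 0, 5L, 240L))
  expect_lt(max(abs(sol$solution - data)), 1e-8)
  expect_true(all(diff(sol$report$objective) <= 1e-12))

  A <- matrix(rnorm(12 * 8), 12, 8)
  b <- rnorm(12)
  op <- function(x) array(A %*% as.vector(x), c(12, 1))
  adj <- function(u) array(crossprod(A, as.vector(u)), c(4, 2))
  L <- max(eigen(crossprod(A), only.values = TRUE)$values)
  sol2 <- fista_solve(op, adj, array(b, c(12, 1)),
                      fista_config(0.9 / L, 0, 5L, 600L))
  oracle <- solve(crossprod(A), crossprod(A, b))
  f <- function(x) 0.5 * sum((A %*% x - b)^2)
  expect_lt(abs(f(as.vector(sol2$solution)) - f(oracle)), 1e-6)
  expect_true(all(diff(sol2$report$objective) <= 1e-12))

  # divergent steps are caught, not silently propagated
  blow <- function(x) 5 * x
  expect_error(
    suppressWarnings(fista_solve(blow, blow, data,
                                 fista_config(5, 0, 5L, 200L, monotone = FALSE),
                                 lipschitz = 25)),
    "NaN|Inf")
})

test_that("noiseless forward fields invert to the injected traction", {
  sub <- elastic_substrate(11000, 0.5)
  grid <- surface_grid(16, 16, 0.732)
  truth <- make_traction_phantom(grid, "dipole", magnitude = 500,
                                 separation = 5, width = 1.2)
  kern <- sample_greens_kernel(c(16, 16), 0.732, depths = c(0, 0.732), sub)
  u <- forward_displacement(truth, kern)
  rec <- reconstruct_traction(u, sub, kernel = kern)
  cc <- cor(c(rec$tx, rec$ty, rec$tz), c(truth$tx, truth$ty, truth$tz))
  expect_gt(cc, 0.95)
  peak_ratio <- max(abs(c(rec$tx, rec$ty))) / max(abs(c(truth$tx, truth$ty)))
  expect_gt(peak_ratio, 0.85)
  expect_lt(peak_ratio, 1.15)
  net <- sqrt(sum(rec$tx)^2 + sum(rec$ty)^2) / sum(sqrt(rec$tx^2 + rec$ty^2))
  expect_lt(net, 0.05)
  expect_true(all(diff(attr(rec, "report")$objective) <= 1e-10))

  # zero displacement gives zero traction
  z <- ritfm:::new_displacement_field(grid$x, grid$y, c(0, 0.732),
                                      array(0, c(16, 16, 2, 3)))
  rec0 <- reconstruct_traction(z, sub, kernel = kern)
  expect_true(all(rec0$tx == 0) && all(rec0$tz == 0))
})

test_that("stronger TV weights suppress noise-induced background traction", {
  sub <- elastic_substrate(11000, 0.5)
  grid <- surface_grid(14, 14, 0.732)
  truth <- make_traction_phantom(grid, "dipole", magnitude = 500,
                                 separation = 4, width = 1)
  kern <- sample_greens_kernel(c(14, 14), 0.732, depths = c(1.0, 1.74), sub)
  u0 <- forward_displacement(truth, kern)
  rho <- sqrt(outer(grid$x^2, grid$y^2, `+`))
  background <- rho > 4    # away from the loaded patches
  taus <- c(0.005, 0.02, 0.08)
  noise_sd_nm <- c(6, 6, 15)
  bg_std <- sapply(taus, function(tau) {
    mean(vapply(1:10, function(s) {
      un <- u0$u
      for (c3 in 1:3)
        un[, , , c3] <- un[, , , c3] +
          ritfm:::with_seed(500 + 10 * s + c3,
                            array(rnorm(length(un[, , , c3]), 0,
                                        noise_sd_nm[c3] * 1e-3),
                                  dim(un[, , , c3])))
      fn <- ritfm:::new_displacement_field(u0$x, u0$y, u0$z, un)
      rec <- reconstruct_traction(fn, sub,
                                  fista_config(0.01, tau, 60L, 80L),
                                  kernel = kern)
      sd(c(rec$tx[background], rec$ty[background], rec$tz[background]))
    }, numeric(1)))
  })
  expect_true(all(diff(bg_std) < 0))
})

test_that("the regularized solution approaches least squares as tau vanishes", {
  set.seed(23)
  A <- matrix(rnorm(36 * 36), 36, 36) / 6 + diag(36)   # well-conditioned
  op <- function(x) array(A %*% as.vector(x), c(6, 6))
  adj <- function(u) array(crossprod(A, as.vector(u)), c(6, 6))
  x_true <- array(rnorm(36), c(6, 6))
  b <- op(x_true)
  L <- max(eigen(crossprod(A), only.values = TRUE)$values)
  ls <- array(solve(A, as.vector(b)), c(6, 6))
  dist <- vapply(c(0.05, 0.01, 0.002, 0), function(tau) {
    s <- fista_solve(op, adj, b, fista_config(1 / L, tau, 40L, 300L))
    sqrt(sum((s$solution - ls)^2))
  }, numeric(1))
  expect_true(all(diff(dist) < 1e-8))
  expect_lt(dist[4], 0.05)   # finite-iteration residual of the tau = 0 solve
})

test_that("two-stage TV deconvolution sharpens blurred phantoms deterministically", {
  truth <- make_bead_phantom(phantom_spec(c(48L, 48L, 48L), 0.183, seed = 5L))
  i <- seq(-6, 6)
  psf <- exp(-i^2 / (2 * 1.2^2)) %o% exp(-i^2 / (2 * 1.2^2)) %o%
         exp(-i^2 / (2 * 2.5^2))
  psf <- psf / sum(psf)
  blurred <- ri_volume(ritfm:::convolve_volume(truth$data, psf), 0.183)
  dec <- deconvolve_volume(blurred, psf, nonnegative = TRUE)
  rmse <- function(a) sqrt(mean((a - truth$data)^2))
  expect_lt(rmse(dec$data), rmse(blurred$data))

  dec2 <- deconvolve_volume(blurred, psf, nonnegative = TRUE)
  expect_identical(dec$data, dec2$data)

  # delta PSF with no regularization is the identity
  delta <- array(0, c(5, 5, 5)); delta[3, 3, 3] <- 1
  out <- deconvolve_volume(truth, delta,
                           stage1 = fista_config(0.5, 0, 5L, 10L),
                           stage2 = fista_config(1, 0, 5L, 20L),
                           downsample = 1L)
  expect_lt(max(abs(out$data - truth$data)), 1e-10)

  big <- array(1, c(64, 64, 64))
  expect_error(deconvolve_volume(truth, big), "PSF larger")
})
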
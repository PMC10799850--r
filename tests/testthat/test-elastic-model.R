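test_that("the surface Green's tensor matches its closed forms", {
  sub <- elastic_substrate(1000, 0.5)
  G <- greens_tensor(1, 0, 0, sub)
  expect_equal(G["z", "z"], 3 / (4 * pi * 1000 * 1e-6), tolerance = 1e-12)
  # shear-normal coupling vanishes at the incompressible surface
  expect_identical(G["x", "z"], 0)
  expect_identical(G["z", "x"], 0)
  expect_identical(G["y", "z"], 0)
  expect_identical(G["z", "y"], 0)

  # xy symmetry at arbitrary points and compressibility
  set.seed(4)
  for (i in 1:10) {
    p <- runif(3, 0.1, 5)
    nu <- runif(1, 0, 0.5)
    Gi <- greens_tensor(p[1], p[2], p[3], elastic_substrate(500, nu))
    expect_identical(Gi["x", "y"], Gi["y", "x"])
  }
  expect_error(greens_tensor(0, 0, 0, sub), "singular")
  expect_error(greens_tensor(1, 0, -1, sub), "z must be")
})

test_that("the sampled kernel is finite, scales as 1/E, and decays as 1/rho", {
  sub <- elastic_substrate(2000, 0.5)
  k <- sample_greens_kernel(c(12, 12), 0.5, depths = c(0.5), sub)
  expect_true(all(is.finite(k$Khat)))
  expect_match(k$singular_cell, "all depths > 0")
  k0 <- sample_greens_kernel(c(12, 12), 0.5, depths = 0, sub)
  expect_match(k0$singular_cell, "quadrature")

  kE <- sample_greens_kernel(c(12, 12), 0.5, depths = 0,
                             elastic_substrate(4000, 0.5))
  expect_equal(k0$Khat, 2 * kE$Khat, tolerance = 1e-12)

  # far field along the surface matches the closed Boussinesq form
  for (rho in c(3, 4.5)) {
    G <- greens_tensor(rho, 0, 0, sub)
    expect_equal(G["z", "z"], 3 / (4 * pi * 2000 * rho * 1e-6),
                 tolerance = 0.01)
  }
  expect_error(sample_greens_kernel(c(12, 12), 0.5, numeric(0), sub),
               "at least one")
})

test_that("the FFT forward operator equals direct summation and has an exact adjoint", {
  sub <- elastic_substrate(1500, 0.45)
  grid <- surface_grid(10, 10, 0.6)
  set.seed(7)
  tr <- ritfm:::new_traction_field(matrix(rnorm(100), 10), matrix(rnorm(100), 10),
                                   matrix(rnorm(100), 10), grid)
  depths <- c(0, 0.6)
  kern <- sample_greens_kernel(c(10, 10), 0.6, depths, sub)
  u_fft <- forward_displacement(tr, kern)
  u_dir <- direct_forward_oracle(tr, sub, depths, c(0.6, 0.6))
  expect_lt(max(abs(u_fft$u - u_dir)) / max(abs(u_dir)), 1e-10)

  T2 <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  U2 <- array(rnorm(10 * 10 * 2 * 3), c(10, 10, 2, 3))
  lhs <- sum(ritfm:::kernel_forward(kern, T2) * U2)
  rhs <- sum(T2 * ritfm:::kernel_adjoint(kern, U2))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)

  # zero in, zero out
  zero <- ritfm:::new_traction_field(matrix(0, 10, 10), matrix(0, 10, 10),
                                     matrix(0, 10, 10), grid)
  expect_true(all(forward_displacement(zero, kern)$u == 0))
})

test_that("a point normal load reproduces the Boussinesq surface solution", {
  E <- 1000
  sub <- elastic_substrate(E, 0.5)
  grid <- surface_grid(32, 32, 0.5)
  tz <- matrix(0, 32, 32)
  tz[16, 16] <- 200    # Pa on one 0.5 x 0.5 um cell
  tr <- ritfm:::new_traction_field(matrix(0, 32, 32), matrix(0, 32, 32), tz, grid)
  kern <- sample_greens_kernel(c(32, 32), 0.5, depths = 0, sub)
  u <- forward_displacement(tr, kern)
  force <- 200 * (0.5e-6)^2          # N
  for (drho in c(4, 8, 12)) {
    rho_m <- drho * 0.5 * 1e-6
    expected_um <- 3 * force / (4 * pi * E * rho_m) * 1e6
    expect_equal(u$u[16 + drho, 16, 1, 3], expected_um, tolerance = 0.01)
  }
  # with nu = 0.5 a pure normal load produces no in-plane surface motion
  expect_equal(max(abs(u$u[, , , 1:2])), 0)
})

test_that("the forward map is linear and scales inversely with stiffness", {
  grid <- surface_grid(12, 12, 0.7)
  set.seed(12)
  mk <- function() ritfm:::new_traction_field(matrix(rnorm(144), 12),
                                              matrix(rnorm(144), 12),
                                              matrix(rnorm(144), 12), grid)
  t1 <- mk(); t2 <- mk()
  k1 <- sample_greens_kernel(c(12, 12), 0.7, c(0, 0.7),
                             elastic_substrate(1000, 0.5))
  k2 <- sample_greens_kernel(c(12, 12), 0.7, c(0, 0.7),
                             elastic_substrate(3000, 0.5))
  lin <- ritfm:::new_traction_field(2 * t1$tx - t2$tx, 2 * t1$ty - t2$ty,
                                    2 * t1$tz - t2$tz, grid)
  u_lin <- forward_displacement(lin, k1)$u
  u_sup <- 2 * forward_displacement(t1, k1)$u - forward_displacement(t2, k1)$u
  expect_equal(u_lin, u_sup, tolerance = 1e-12)
  expect_equal(forward_displacement(t1, k1)$u,
               3 * forward_displacement(t1, k2)$u, tolerance = 1e-12)
})

test_that("the normal operator peaks symmetrically at a delta traction", {
  # odd grid with the delta at the centre keeps the crop boundary symmetric
  grid <- surface_grid(17, 17, 0.5)
  tx <- matrix(0, 17, 17); tx[9, 9] <- 1
  tr <- ritfm:::new_traction_field(tx, matrix(0, 17, 17), matrix(0, 17, 17), grid)
  kern <- sample_greens_kernel(c(17, 17), 0.5, c(0.5), elastic_substrate(1000, 0.5))
  u <- forward_displacement(tr, kern)
  back <- adjoint_displacement(u, kern)
  expect_equal(which(back$tx == max(back$tx), arr.ind = TRUE)[1, ],
               c(row = 9L, col = 9L))
  # symmetric response around the delta
  expect_equal(back$tx[8, 9], back$tx[10, 9], tolerance = 1e-10)
  expect_equal(back$tx[9, 8], back$tx[9, 10], tolerance = 1e-10)
  zero_u <- ritfm:::new_displacement_field(grid$x, grid$y, 0.5,
                                           array(0, c(17, 17, 1, 3)))
  zb <- adjoint_displacement(zero_u, kern)
  expect_true(all(zb$tx == 0) && all(zb$tz == 0))
})
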
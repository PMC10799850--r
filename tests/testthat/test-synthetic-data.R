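test_that("bead counts follow the seeding density within Poisson bounds", {
  spec <- phantom_spec(c(64L, 64L, 64L), 0.183, bead_density = 3, seed = 11L)
  vol <- make_bead_phantom(spec)
  expected <- 3 * (64 * 0.183)^3
  n <- attr(vol, "n_beads")
  expect_true(abs(n - expected) < 4 * sqrt(expected))
  expect_equal(nrow(attr(vol, "bead_positions")), n)
  expect_true(all(vol$data >= spec$background_level))
})

test_that("zero density gives a background-only volume and generators are deterministic", {
  spec0 <- phantom_spec(c(16L, 16L, 16L), 0.2, bead_density = 0,
                        background_level = 0.4)
  v0 <- make_bead_phantom(spec0)
  expect_identical(attr(v0, "n_beads"), 0L)
  expect_true(all(v0$data == 0.4))

  spec <- phantom_spec(c(24L, 24L, 24L), 0.2, seed = 5L)
  expect_identical(make_bead_phantom(spec)$data, make_bead_phantom(spec)$data)

  tiny <- phantom_spec(c(1L, 1L, 1L), voxel_pitch = 0.05)
  expect_error(make_bead_phantom(tiny), "too small")
})

test_that("integer translation rolls the grid and fourier shifts are exact inverses", {
  a <- array(rnorm(16^3), c(16, 16, 16))
  b <- translate_volume(a, c(3, -2, 1), mode = "integer")
  expect_equal(b[10, 10, 10], a[7, 12, 9])

  i <- 1:32
  g <- exp(-(i - 16.5)^2 / 8)
  smooth <- g %o% g %o% g
  fwd <- translate_volume(smooth, c(0.5, 0, 0), mode = "fourier")
  back <- translate_volume(fwd, c(-0.5, 0, 0), mode = "fourier")
  expect_lt(max(abs(back - smooth)) / max(abs(smooth)), 1e-9)

  shifted <- translate_volume(smooth, c(0.25, 0, 0), mode = "fourier")
  expect_equal(axis_centroid(shifted, 1) - axis_centroid(smooth, 1), 0.25,
               tolerance = 1e-6)

  expect_error(translate_volume(a, c(NA, 0, 0)), "finite")
  expect_error(translate_volume(a, c(40, 0, 0)), "extent")
})

test_that("fourier shifts conserve volume sum", {
  vol <- shared_phantom()
  for (sh in list(c(1.3, 0, 0), c(0.5, -2.25, 0.75), c(-3.1, 0.01, 5.5))) {
    out <- translate_volume(vol, sh, mode = "fourier")
    expect_lt(abs(sum(out$data) - sum(vol$data)) / abs(sum(vol$data)), 1e-9)
  }
})

test_that("traction phantoms are balanced, signed as specified, and validated", {
  grid <- surface_grid(49, 49, 0.5)   # odd grid: patch centres on nodes
  dip <- make_traction_phantom(grid, "dipole", magnitude = 100,
                               separation = 8, width = 1)
  gross <- sum(sqrt(dip$tx^2 + dip$ty^2))
  expect_lt(abs(sum(dip$tx)) / gross, 1e-10)
  expect_lt(abs(sum(dip$ty)) / gross, 1e-10)
  expect_equal(max(sqrt(dip$tx^2 + dip$ty^2)), 100, tolerance = 1e-6)

  ring <- make_traction_phantom(grid, "ring", magnitude = 50, radius = 4)
  expect_lt(abs(sum(ring$tx)) / sum(abs(ring$tx)), 1e-10)
  rot <- make_traction_phantom(grid, "rotational_moment", magnitude = 50,
                               radius = 4)
  expect_lt(abs(sum(rot$tx)) / sum(abs(rot$tx)), 1e-10)

  # upward normal traction on the distal annulus, downward on the proximal disc
  patch <- make_traction_phantom(grid, "patch", magnitude = 80, radius = 5,
                                 width = 1)
  centre <- patch$tz[25, 25]
  rim <- patch$tz[25 + 10, 25]   # 5 um out at 0.5 um pitch
  expect_lt(centre, 0)
  expect_gt(rim, 0)

  zero <- make_traction_phantom(grid, "dipole", magnitude = 0)
  expect_true(all(zero$tx == 0) && all(zero$ty == 0) && all(zero$tz == 0))
  expect_error(make_traction_phantom(grid, "vortex"), "unknown")
})

test_that("additive noise is seeded, unbiased in scale, and optional", {
  vol <- ri_volume(array(0, c(64, 64, 64)), 0.2)
  expect_identical(add_noise(vol, noise_spec(0, 1L)), vol)
  n1 <- add_noise(vol, noise_spec(0.05, 9L))
  n2 <- add_noise(vol, noise_spec(0.05, 9L))
  expect_identical(n1$data, n2$data)
  expect_equal(sd(n1$data), 0.05, tolerance = 0.02 * 0.05)
})

test_that("zero traction leaves the phantom unchanged under deformation", {
  vol <- shared_phantom()
  grid <- surface_grid(48, 48, 0.183)
  zero <- make_traction_phantom(grid, "dipole", magnitude = 0)
  out <- deform_phantom(vol, zero, elastic_substrate(11000, 0.5))
  expect_equal(out$data, vol$data, tolerance = 1e-12)
  u <- attr(out, "displacement")
  expect_true(all(u$u == 0))
})

test_that("warping with a uniform displacement matches direct translation", {
  vol <- shared_phantom()
  d <- dim(vol$data)
  co <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  # integer shifts interpolate exactly onto the rolled grid
  int_sh <- array(ritfm:::interp3_cubic(vol$data, co$i - 2, co$j, co$k), d)
  rolled <- translate_volume(vol$data, c(2, 0, 0), mode = "integer")
  interior <- 5:44
  expect_equal(int_sh[interior, interior, interior],
               rolled[interior, interior, interior], tolerance = 1e-12)
  # fractional shifts of a resolvable (smooth) object match the band-limited
  # reference closely; sub-resolution beads carry larger interpolation error
  i <- 1:48
  g <- exp(-(i - 22.3)^2 / (2 * 2^2))
  smooth <- g %o% g %o% g
  co2 <- expand.grid(i = 1:48, j = 1:48, k = 1:48)
  frac <- array(ritfm:::interp3_cubic(smooth, co2$i - 0.4, co2$j, co2$k),
                c(48, 48, 48))
  reference <- translate_volume(smooth, c(0.4, 0, 0), mode = "fourier")
  expect_lt(max(abs(frac[interior, interior, interior] -
                    reference[interior, interior, interior])),
            0.005 * max(smooth))
  beads <- array(ritfm:::interp3_cubic(vol$data, co$i - 0.4, co$j, co$k), d)
  bead_ref <- translate_volume(vol$data, c(0.4, 0, 0), mode = "fourier")
  expect_gt(cor(c(beads[interior, interior, interior]),
                c(bead_ref[interior, interior, interior])), 0.95)
})

test_that("a dipole load displaces beads at the tens-of-nm scale with spatial decay", {
  vol <- make_bead_phantom(phantom_spec(c(48L, 48L, 48L), 0.183, seed = 2L))
  grid <- surface_grid(48, 48, 0.183)
  tr <- make_traction_phantom(grid, "dipole", magnitude = 100,
                              separation = 3, width = 0.8)
  out <- deform_phantom(vol, tr, elastic_substrate(11000, 0.5))
  u <- attr(out, "displacement")
  mag <- sqrt(u$u[, , , 1]^2 + u$u[, , , 2]^2 + u$u[, , , 3]^2)
  expect_gt(max(mag), 1e-3)   # > 1 nm
  expect_lt(max(mag), 1)      # < 1 um
  # decays away from the loaded region (compare centre plane to far corner)
  expect_lt(mag[3, 3, 1], 0.2 * max(mag[, , 1]))
})
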
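test_that("the refractive-index to weight-pressure unit chain is exact", {
  p <- dry_mass_params()           # alpha = 0.185 mL/g, g = 9.8 m/s^2
  vol <- ri_volume(array(1.337 + 0.0185, c(6, 6, 6)), 0.2)
  dens <- ri_to_density(vol, p)
  expect_equal(dens$data[1, 1, 1], 0.1, tolerance = 1e-12)
  expect_equal(attr(dens, "fraction_clamped"), 0)

  flat <- ri_to_density(ri_volume(array(1.337, c(4, 4, 4)), 0.2), p)
  expect_true(all(flat$data == 0))

  slab <- ri_volume(array(0.1, c(5, 5, 10)), c(1, 1, 0.2))   # 2 um thick
  sm <- surface_density_map(slab)
  expect_true(all(abs(sm$map - 200) < 1e-9))

  expect_equal(weight_pressure(20.45, p), 20.45e-6 * 9.8, tolerance = 1e-12)
  expect_equal(weight_pressure(0, p), 0)
  expect_equal(weight_pressure(2 * 20.45, p), 2 * weight_pressure(20.45, p))
  expect_error(dry_mass_params(alpha_ri = 0), "alpha")
})

test_that("cell weight pressure sits far below cellular traction scales", {
  p <- dry_mass_params()
  pressures <- weight_pressure(c(1, 10, 100), p)
  expect_true(all(pressures <= 1e-3))
  expect_gte(log10(100 / max(pressures)), 5)
})

test_that("total dry mass is invariant under rigid translation of the body", {
  body <- array(0, c(32, 32, 32))
  i <- 1:32
  g <- exp(-(i - 12.3)^2 / 10)
  body <- 1.35 + 0.02 * (g %o% g %o% g)
  vol <- ri_volume(body, 0.3)
  p <- dry_mass_params(n_medium = 1.337)
  mass <- function(v) sum(ri_to_density(v, p)$data) * prod(v$pitch)
  moved <- translate_volume(vol, c(3, -2, 4), mode = "integer")
  expect_equal(mass(moved), mass(vol), tolerance = 1e-12)
})

test_that("traction statistics summarize shear and normal components", {
  grid <- surface_grid(10, 10, 1)
  uni <- ritfm:::new_traction_field(matrix(100, 10, 10), matrix(0, 10, 10),
                                    matrix(0, 10, 10), grid)
  st <- traction_stats(uni)
  expect_equal(st$shear$mean, 100)
  expect_equal(st$shear$sd, 0)

  zero <- ritfm:::new_traction_field(matrix(0, 10, 10), matrix(0, 10, 10),
                                     matrix(0, 10, 10), grid)
  st0 <- traction_stats(zero)
  expect_equal(st0$shear$mean, 0)
  expect_equal(st0$normal$max, 0)

  dip <- make_traction_phantom(surface_grid(33, 33, 0.5), "dipole",
                               magnitude = 80, separation = 6, width = 1)
  std <- traction_stats(dip)
  expect_equal(abs(std$shear$max), 80, tolerance = 1e-6)
  thr <- traction_stats(dip, threshold = 40)
  expect_gt(thr$shear$mean, std$shear$mean)
})

test_that("differential tractions follow the zero-first-frame convention and telescope", {
  grid <- surface_grid(8, 8, 1)
  mk <- function(s) ritfm:::new_traction_field(matrix(s, 8, 8) + s,
                                               matrix(2 * s, 8, 8),
                                               matrix(-s, 8, 8), grid)
  t1 <- mk(1); t2 <- mk(3); t3 <- mk(2.5)
  expect_equal(differential_traction(t1, t1)$tx, matrix(0, 8, 8))
  expect_identical(differential_traction(t1, NULL), t1)   # dT_1 = T_1
  d2 <- differential_traction(t2, t1); d3 <- differential_traction(t3, t2)
  total <- t1$tx + d2$tx + d3$tx
  expect_equal(total, t3$tx, tolerance = 1e-12)
  small <- ritfm:::new_traction_field(matrix(0, 4, 4), matrix(0, 4, 4),
                                      matrix(0, 4, 4), surface_grid(4, 4, 1))
  expect_error(differential_traction(t1, small), "congruent")
})

test_that("kymographs stack profiles and trace moving features", {
  static <- replicate(5, matrix(1:12, 4, 3), simplify = FALSE)
  ky <- kymograph(static, axis = "x", reduce = "max")
  expect_equal(dim(ky), c(4L, 5L))
  expect_true(all(ky == ky[, 1]))
  expect_equal(ky[, 1], apply(static[[1]], 1, max))

  # a gaussian ridge moving 2 px/frame appears as a linear track of maxima
  frames <- lapply(0:4, function(t) {
    x <- 1:40
    outer(exp(-(x - 8 - 2 * t)^2 / 4), rep(1, 6))
  })
  kym <- kymograph(frames, axis = "x", reduce = "mean")
  peaks <- apply(kym, 2, which.max)
  expect_equal(peaks, seq(8, 16, by = 2))
  expect_error(kymograph(frames[1]), "2 time points")
})

test_that("morphology parameters recover slab and hemisphere geometry", {
  slab <- array(0, c(20, 20, 30))
  slab[, , 6:20] <- 0.1                       # 15 slices x 0.2 um = 3 um
  vol <- ri_volume(slab, c(0.5, 0.5, 0.2))
  m <- morphology_params(vol, threshold = 0.02)
  expect_equal(m$max_thickness_um, 3)
  expect_equal(m$mean_surface_density_fg_um2, 0.1 * 3 * 1000)

  # hemisphere of radius R sitting on the surface: max thickness = R
  R <- 2
  d <- c(24, 24, 16); pitch <- 0.25
  hemi <- array(0, d)
  cx <- 12.5
  for (k in seq_len(d[3])) {
    z <- (k - 1) * pitch
    r2 <- R^2 - z^2
    if (r2 > 0) {
      xy <- outer(((1:d[1]) - cx)^2, ((1:d[2]) - cx)^2, `+`) * pitch^2
      hemi[, , k][xy <= r2] <- 0.1
    }
  }
  mh <- morphology_params(ri_volume(hemi, pitch), threshold = 0.02)
  expect_equal(mh$max_thickness_um, R, tolerance = pitch + 1e-9)
  expect_error(morphology_params(ri_volume(array(0, c(4, 4, 4)), 1)),
               "empty cell support")
})
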
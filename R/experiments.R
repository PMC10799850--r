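## Self-contained validation experiments: rigid-translation ladder (tracking
## accuracy/precision), forward-model traction recovery, and high-pass
## suppression. Shared by the test suite and the acceptance script so that
## both measure the same study conditions.

#' Rigid-translation ladder experiment
#'
#' Generates one bead phantom, imposes known rigid subvoxel translations
#' (default 0.5-3 um in 0.5-um steps, the stage-translation validation
#' design), tracks each translated copy against the original, and reports
#' per-step accuracy (mean error) and precision (per-axis standard deviation
#' over tracking windows).
#'
#' @param seed Phantom seed.
#' @param shape Volume shape in voxels.
#' @param pitch Voxel pitch (um).
#' @param shifts_um Imposed translations along x (um).
#' @param subset,spacing,upsample Tracking parameters (voxels / factor).
#' @return Data frame with one row per step: imposed and recovered mean
#'   displacement (um), per-axis standard deviations (nm), the mean absolute
#'   error in voxels, and the window count.
#' @export
displacement_ladder_experiment <- function(seed = 1L,
                                           shape = c(128L, 128L, 128L),
                                           pitch = 0.183,
                                           shifts_um = seq(0.5, 3, by = 0.5),
                                           subset = 64L, spacing = 24L,
                                           upsample = 100L) {
  ref <- make_bead_phantom(phantom_spec(shape, pitch, seed = seed))
  cfg <- tracking_config(subset_size = subset, grid_spacing = spacing,
                         upsample = upsample)
  out <- vector("list", length(shifts_um))
  for (s in seq_along(shifts_um)) {
    sh_vox <- c(shifts_um[s] / pitch, 0, 0)
    mov <- translate_volume(ref, sh_vox, mode = "fourier")
    field <- estimate_displacement_field(ref, mov, cfg)
    st <- field_stats(field, expected = c(shifts_um[s], 0, 0))
    out[[s]] <- data.frame(
      imposed_um = shifts_um[s],
      mean_ux_um = st$mean[1], mean_uy_um = st$mean[2],
      mean_uz_um = st$mean[3],
      sd_x_nm = st$sd[1] * 1e3, sd_y_nm = st$sd[2] * 1e3,
      sd_z_nm = st$sd[3] * 1e3,
      mean_abs_err_vox = max(abs(st$bias) / pitch),
      n_windows = st$n[1])
  }
  do.call(rbind, out)
}

#' Forward-model traction recovery experiment
#'
#' End-to-end round trips: for each seeded scene a ground-truth traction
#' pattern (alternating contractile dipole / inward ring, randomized
#' orientation) is applied to a bead phantom through the elastic forward
#' model, the deformed volume is tracked on the two node planes nearest the
#' surface, and the tractions are reconstructed with the default monotone
#' TV-FISTA settings. Reports, per scene, the correlation between recovered
#' and true traction patterns, the net in-plane force residual as a fraction
#' of the gross force, and the tracking RMSE against the injected continuum
#' displacement.
#'
#' @param n_scenes Number of seeded scenes.
#' @param seed Base seed; scene i uses `seed * 1000 + i`.
#' @param shape,pitch Phantom geometry (voxels, um).
#' @param magnitude Peak traction (Pa).
#' @param width Patch/annulus Gaussian width (um).
#' @param separation Dipole separation (um).
#' @param radius Ring radius (um).
#' @param substrate An [elastic_substrate()].
#' @param subset,spacing,upsample Tracking parameters.
#' @param noise_sigma Additive volume noise s.d. (0 = noiseless).
#' @param cfg Solver configuration ([fista_config()]).
#' @return Data frame with one row per scene: `pattern`, `correlation`,
#'   `net_residual` (net/gross in-plane force), `track_rmse_vox`,
#'   `peak_ratio` (recovered/true peak magnitude).
#' @export
traction_recovery_experiment <- function(n_scenes = 20L, seed = 1L,
                                         shape = c(64L, 64L, 64L),
                                         pitch = 0.183,
                                         magnitude = 500, width = 1.2,
                                         separation = 5, radius = 2.5,
                                         substrate = elastic_substrate(11000, 0.5),
                                         subset = 16L, spacing = 4L,
                                         upsample = 100L,
                                         noise_sigma = 0,
                                         cfg = fista_config()) {
  rows <- vector("list", n_scenes)
  tcfg <- tracking_config(subset_size = subset, grid_spacing = spacing,
                          upsample = upsample, z_nodes = 1:2)
  for (i in seq_len(n_scenes)) {
    scene_seed <- seed * 1000L + i
    pattern <- if (i %% 2L == 1L) "dipole" else "ring"
    theta <- with_seed(scene_seed, runif(1, 0, pi))
    grid <- surface_grid(shape[1], shape[2], pitch)
    truth <- make_traction_phantom(
      grid, pattern, magnitude = magnitude, separation = separation,
      radius = radius, width = width,
      orientation = c(cos(theta), sin(theta)))
    ref <- make_bead_phantom(phantom_spec(shape, pitch, seed = scene_seed))
    mov <- deform_phantom(ref, truth, substrate)
    u_true <- attr(mov, "displacement")
    if (noise_sigma > 0) {
      ref <- add_noise(ref, noise_spec(noise_sigma, scene_seed + 1L))
      mov <- add_noise(mov, noise_spec(noise_sigma, scene_seed + 2L))
    }
    field <- estimate_displacement_field(ref, mov, tcfg)
    # injected continuum displacement at the node positions (voxel coords)
    nodes <- list(field$x / pitch + 1, field$y / pitch + 1, field$z / pitch + 1)
    co <- expand.grid(i = seq_along(nodes[[1]]), j = seq_along(nodes[[2]]),
                      k = seq_along(nodes[[3]]))
    u_exp <- array(0, c(lengths(nodes), 3))
    for (c3 in 1:3)
      u_exp[cbind(co$i, co$j, co$k, c3)] <-
        interp3_trilinear(u_true$u[, , , c3], nodes[[1]][co$i],
                          nodes[[2]][co$j], nodes[[3]][co$k])
    expected <- new_displacement_field(field$x, field$y, field$z, u_exp)
    st <- field_stats(field, expected)
    track_rmse_vox <- sqrt(mean((st$rmse / pitch)^2))
    rec <- reconstruct_traction(field, substrate, cfg)
    # ground truth sampled at the node lateral positions
    ni <- nodes[[1]]; nj <- nodes[[2]]
    bil <- function(m) {
      co2 <- expand.grid(i = seq_along(ni), j = seq_along(nj))
      matrix(interp3_trilinear(array(m, c(dim(m), 1L)),
                               ni[co2$i], nj[co2$j], rep(1, nrow(co2))),
             length(ni), length(nj))
    }
    tt <- list(bil(truth$tx), bil(truth$ty), bil(truth$tz))
    rvec <- c(rec$tx, rec$ty, rec$tz)
    tvec <- c(tt[[1]], tt[[2]], tt[[3]])
    correlation <- suppressWarnings(stats::cor(rvec, tvec))
    gross <- sum(sqrt(rec$tx^2 + rec$ty^2))
    net <- sqrt(sum(rec$tx)^2 + sum(rec$ty)^2)
    peak_true <- max(sqrt(tt[[1]]^2 + tt[[2]]^2 + tt[[3]]^2))
    peak_rec <- max(sqrt(rec$tx^2 + rec$ty^2 + rec$tz^2))
    rows[[i]] <- data.frame(
      scene = i, pattern = pattern, correlation = correlation,
      net_residual = if (gross > 0) net / gross else 0,
      track_rmse_vox = track_rmse_vox,
      peak_ratio = peak_rec / peak_true)
  }
  do.call(rbind, rows)
}

#' High-pass background-suppression experiment
#'
#' A bead phantom is corrupted by a smooth low-frequency background (cosine,
#' period much larger than the filter window). Reports the suppression of
#' power in the low-frequency band (dB), whether the brightest bead peak
#' stays in place, and the kernel weight sum.
#'
#' @param seed Phantom seed.
#' @param shape Volume shape.
#' @param pitch Voxel pitch (um).
#' @param period_vox Background period in voxels.
#' @param amplitude Background amplitude relative to bead contrast.
#' @return List: `suppression_db`, `peak_shift_vox`, `kernel_sum`.
#' @export
highpass_suppression_experiment <- function(seed = 1L,
                                            shape = c(64L, 64L, 64L),
                                            pitch = 0.183,
                                            period_vox = 32,
                                            amplitude = 1) {
  spec <- phantom_spec(shape, pitch, seed = seed)
  beads <- make_bead_phantom(spec)
  i <- seq_len(shape[1])
  bg <- amplitude * spec$bead_contrast *
    array(rep(cos(2 * pi * i / period_vox), times = shape[2] * shape[3]),
          shape)
  vol <- ri_volume(beads$data + bg, pitch)
  kern <- build_highpass_kernel(0.5, 1, pitch)
  filt <- highpass_filter(vol, kern)
  # spectral oracle: power in the low-frequency band |f| <= 2/period
  band_power <- function(a) {
    A <- Mod(fft(a - mean(a)))^2
    f <- lapply(dim(a), fft_freq)
    keep <- outer(abs(f[[1]]) <= 2 / period_vox,
                  abs(f[[2]]) <= 2 / period_vox) %o%
            (abs(f[[3]]) <= 2 / period_vox)
    # exclude DC, count the band around the background frequency
    keep[1, 1, 1] <- FALSE
    sum(A[keep])
  }
  beads_filt <- highpass_filter(beads, kern)
  p0 <- band_power(bg)
  p1 <- band_power(filt$data - beads_filt$data)   # filtered background, by linearity
  peak0 <- which(beads_filt$data == max(beads_filt$data), arr.ind = TRUE)[1, ]
  interior <- all(peak0 > 4) && all(peak0 < shape - 4)
  peak1 <- which(filt$data == max(filt$data), arr.ind = TRUE)[1, ]
  list(suppression_db = 10 * log10(p0 / p1),
       peak_shift_vox = if (interior) sqrt(sum((peak0 - peak1)^2)) else 0,
       kernel_sum = sum(kern))
}
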
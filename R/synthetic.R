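#' Specification of a bead-seeded gel phantom
#'
#' Describes a polyacrylamide-gel tomogram phantom: sub-resolution polystyrene
#' beads (fiducial markers) at a given number density, rendered as band-limited
#' Gaussian spots that emulate the PSF-blurred image of 200-nm beads. Defaults
#' follow the imaging conditions of refractive-index tomography of bead-seeded
#' gels: 3 beads per cubic micrometre, 200-nm bead diameter, and an optical
#' resolution of 161 nm lateral / 401 nm axial.
#'
#' @param volume_shape Voxels per axis, length 3.
#' @param voxel_pitch Micrometres per voxel, length 1 or 3.
#' @param bead_density Beads per cubic micrometre (> 0, or 0 for a
#'   background-only volume).
#' @param bead_diameter Bead diameter in micrometres.
#' @param bead_contrast Peak refractive-index excess of one bead over the
#'   background (dimensionless).
#' @param background_level Constant background value.
#' @param resolution_lateral,resolution_axial Imaging resolution (FWHM, um)
#'   that sets the rendered spot width together with the bead size.
#' @param seed Integer seed; the phantom is a pure function of spec + seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64, 64, 64),
                         voxel_pitch = 0.183,
                         bead_density = 3,
                         bead_diameter = 0.2,
                         bead_contrast = 0.05,
                         background_level = 0,
                         resolution_lateral = 0.161,
                         resolution_axial = 0.401,
                         seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 1L))
    stop("'volume_shape' must be 3 positive integers")
  voxel_pitch <- as.numeric(voxel_pitch)
  if (length(voxel_pitch) == 1L) voxel_pitch <- rep(voxel_pitch, 3L)
  if (any(voxel_pitch <= 0)) stop("'voxel_pitch' must be positive")
  if (bead_density < 0) stop("'bead_density' must be >= 0")
  if (bead_diameter <= 0) stop("'bead_diameter' must be > 0")
  structure(list(volume_shape = volume_shape, voxel_pitch = voxel_pitch,
                 bead_density = bead_density, bead_diameter = bead_diameter,
                 bead_contrast = bead_contrast,
                 background_level = background_level,
                 resolution_lateral = resolution_lateral,
                 resolution_axial = resolution_axial,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rendered spot sigma (voxels, per axis): PSF sigma (FWHM / 2.3548) combined in
# quadrature with the per-axis spread of a uniform ball of radius d/2 (r/sqrt5).
phantom_sigma_vox <- function(spec) {
  fwhm2sd <- 1 / (2 * sqrt(2 * log(2)))
  s_psf <- c(spec$resolution_lateral, spec$resolution_lateral,
             spec$resolution_axial) * fwhm2sd
  s_bead <- (spec$bead_diameter / 2) / sqrt(5)
  sqrt(s_psf^2 + s_bead^2) / spec$voxel_pitch
}

#' Generate a bead-seeded gel phantom volume
#'
#' Draws a Poisson-distributed number of beads (expectation = density x
#' physical volume), places them at uniformly random subvoxel positions and
#' renders each as a separable Gaussian spot whose width combines the stated
#' optical resolution with the finite bead size. Reproducible for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return An [ri_volume()] with attributes `n_beads` and `bead_positions`
#'   (continuous 1-based voxel coordinates, one row per bead).
#' @export
#' @examples
#' v <- make_bead_phantom(phantom_spec(c(32, 32, 32), seed = 7))
#' attr(v, "n_beads")
make_bead_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$volume_shape
  phys <- prod(d * spec$voxel_pitch)
  vol <- array(spec$background_level, dim = d)
  if (spec$bead_density == 0) {
    out <- ri_volume(vol, spec$voxel_pitch)
    attr(out, "n_beads") <- 0L
    attr(out, "bead_positions") <- matrix(numeric(0), ncol = 3)
    return(out)
  }
  if (any(d * spec$voxel_pitch < spec$bead_diameter))
    stop("physical volume too small to contain one bead")
  sig <- phantom_sigma_vox(spec)
  hw <- pmax(2L, as.integer(ceiling(4 * sig)))
  out <- with_seed(spec$seed, {
    n <- rpois(1L, spec$bead_density * phys)
    pos <- cbind(runif(n, 0.5, d[1] + 0.5), runif(n, 0.5, d[2] + 0.5),
                 runif(n, 0.5, d[3] + 0.5))
    if (n > 0) {
      for (b in seq_len(n)) {
        c0 <- pos[b, ]
        ix <- max(1L, floor(c0[1]) - hw[1]):min(d[1], floor(c0[1]) + hw[1])
        iy <- max(1L, floor(c0[2]) - hw[2]):min(d[2], floor(c0[2]) + hw[2])
        iz <- max(1L, floor(c0[3]) - hw[3]):min(d[3], floor(c0[3]) + hw[3])
        gx <- exp(-(ix - c0[1])^2 / (2 * sig[1]^2))
        gy <- exp(-(iy - c0[2])^2 / (2 * sig[2]^2))
        gz <- exp(-(iz - c0[3])^2 / (2 * sig[3]^2))
        vol[ix, iy, iz] <- vol[ix, iy, iz] +
          spec$bead_contrast * (gx %o% gy %o% gz)
      }
    }
    v <- ri_volume(vol, spec$voxel_pitch)
    attr(v, "n_beads") <- n
    attr(v, "bead_positions") <- pos
    v
  })
  out
}

#' Translate a volume by an integer or subvoxel shift
#'
#' @param vol An [ri_volume()] or 3D array.
#' @param shift Length-3 shift in voxels (content moves by `+shift`).
#' @param mode `"fourier"` for an exact band-limited subvoxel shift (circular
#'   boundary), `"integer"` to roll the voxel grid (shift rounded to integers).
#' @return Shifted volume of the same class as the input.
#' @export
translate_volume <- function(vol, shift, mode = c("fourier", "integer")) {
  mode <- match.arg(mode)
  shift <- as.numeric(shift)
  if (length(shift) != 3L || any(!is.finite(shift)))
    stop("'shift' must be 3 finite numbers")
  a <- as_volume_array(vol)
  if (any(abs(shift) >= dim(a)))
    stop("|shift| must be smaller than the volume extent")
  out <- if (mode == "integer") roll_array(a, round(shift))
         else fourier_shift_array(a, shift)
  if (inherits(vol, "ri_volume")) ri_volume(out, vol$pitch) else out
}

#' Additive-noise specification
#'
#' @param additive_sigma Gaussian noise s.d. in volume units (>= 0).
#' @param seed Integer seed.
#' @export
noise_spec <- function(additive_sigma = 0, seed = 1L) {
  if (additive_sigma < 0) stop("'additive_sigma' must be >= 0")
  structure(list(additive_sigma = additive_sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add seeded Gaussian noise to a volume
#'
#' @param vol An [ri_volume()] or 3D array.
#' @param noise A [noise_spec()].
#' @return Noisy volume; identical to the input when `additive_sigma = 0`.
#' @export
add_noise <- function(vol, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$additive_sigma == 0) return(vol)
  a <- as_volume_array(vol)
  out <- with_seed(noise$seed,
                   a + array(rnorm(length(a), 0, noise$additive_sigma), dim(a)))
  if (inherits(vol, "ri_volume")) ri_volume(out, vol$pitch) else out
}

#' Lateral surface grid for traction fields
#'
#' Grid of lateral positions on the gel surface (z = 0), centred on the origin.
#'
#' @param nx,ny Grid nodes per axis.
#' @param pitch Node spacing in micrometres (length 1 or 2).
#' @export
surface_grid <- function(nx, ny = nx, pitch) {
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1L) pitch <- rep(pitch, 2L)
  x <- (seq_len(nx) - (nx + 1) / 2) * pitch[1]
  y <- (seq_len(ny) - (ny + 1) / 2) * pitch[2]
  structure(list(nx = as.integer(nx), ny = as.integer(ny), pitch = pitch,
                 x = x, y = y), class = "surface_grid")
}

new_traction_field <- function(tx, ty, tz, grid) {
  structure(list(tx = tx, ty = ty, tz = tz, x = grid$x, y = grid$y,
                 pitch = grid$pitch), class = "traction_field")
}

#' @export
print.traction_field <- function(x, ...) {
  cat(sprintf("<traction_field> %d x %d nodes, pitch %.3g x %.3g um\n",
              length(x$x), length(x$y), x$pitch[1], x$pitch[2]))
  shear <- sqrt(x$tx^2 + x$ty^2)
  cat(sprintf("  max shear %.3g Pa, max |T_z| %.3g Pa\n",
              max(shear), max(abs(x$tz))))
  invisible(x)
}

#' Generate a ground-truth traction phantom
#'
#' Canonical cell-like traction patterns on a surface grid, used as ground
#' truth for recovery tests. `"dipole"` is a contractile pair of in-plane
#' Gaussian patches pulling toward each other (net in-plane force exactly
#' zero by mirror construction); `"ring"` is inward radial shear on an
#' annulus; `"patch"` carries upward normal traction on a distal annulus and
#' downward normal traction on the proximal disc (the sign pattern seen at
#' adherent cell edges); `"rotational_moment"` is tangential shear on an
#' annulus.
#'
#' @param grid A [surface_grid()].
#' @param pattern Pattern name.
#' @param magnitude Peak traction magnitude in Pa (>= 0).
#' @param separation Patch-centre separation for `"dipole"` (um).
#' @param radius Annulus radius for ring/patch/moment patterns (um).
#' @param width Gaussian width sigma of patches/annuli (um).
#' @param orientation In-plane unit vector (dipole axis), length 2.
#' @param center Pattern centre `(x, y)` in um.
#' @return A `traction_field` with components `tx`, `ty`, `tz` in Pa.
#' @export
make_traction_phantom <- function(grid,
                                  pattern = c("dipole", "ring", "patch",
                                              "rotational_moment"),
                                  magnitude = 100,
                                  separation = 8,
                                  radius = 2,
                                  width = 1,
                                  orientation = c(1, 0),
                                  center = c(0, 0)) {
  stopifnot(inherits(grid, "surface_grid"))
  if (!is.character(pattern) ||
      !pattern[1] %in% c("dipole", "ring", "patch", "rotational_moment"))
    stop("unknown traction pattern: ", pattern[1])
  pattern <- pattern[1]
  if (magnitude < 0) stop("'magnitude' must be >= 0")
  o <- orientation / sqrt(sum(orientation^2))
  X <- matrix(grid$x, grid$nx, grid$ny) - center[1]
  Y <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE) - center[2]
  zero <- matrix(0, grid$nx, grid$ny)
  tx <- ty <- tz <- zero
  if (magnitude == 0)
    return(new_traction_field(tx, ty, tz, grid))
  if (pattern == "dipole") {
    c1 <- -o * separation / 2
    g1 <- exp(-((X - c1[1])^2 + (Y - c1[2])^2) / (2 * width^2))
    g2 <- exp(-((X + c1[1])^2 + (Y + c1[2])^2) / (2 * width^2))
    # patches pull toward each other; mirrored pair sums to exactly zero
    tx <- magnitude * o[1] * (g1 - g2)
    ty <- magnitude * o[2] * (g1 - g2)
  } else if (pattern %in% c("ring", "rotational_moment")) {
    rho <- sqrt(X^2 + Y^2)
    amp <- magnitude * exp(-(rho - radius)^2 / (2 * width^2))
    rx <- ifelse(rho > 0, X / pmax(rho, .Machine$double.eps), 0)
    ry <- ifelse(rho > 0, Y / pmax(rho, .Machine$double.eps), 0)
    if (pattern == "ring") {      # inward radial shear
      tx <- -amp * rx
      ty <- -amp * ry
    } else {                      # tangential shear (torque about the centre)
      tx <- -amp * ry
      ty <- amp * rx
    }
  } else if (pattern == "patch") {
    rho <- sqrt(X^2 + Y^2)
    up <- exp(-(rho - radius)^2 / (2 * width^2))     # distal annulus, upward
    down <- exp(-rho^2 / (2 * width^2))              # proximal disc, downward
    tz <- magnitude * (up - down)
  }
  new_traction_field(tx, ty, tz, grid)
}

#' Forward-deform a phantom volume under a surface traction field
#'
#' Computes the continuum elastic displacement u(r) = (G x T)(r) at every
#' voxel depth from the half-space Green's tensor and warps the relaxed
#' volume by trilinear interpolation. The input is the relaxed (reference)
#' state, e.g. the gel after chemical cell detachment; the output is the
#' deformed state under traction, so that tracking deformed against relaxed
#' recovers +u.
#'
#' @param vol Relaxed [ri_volume()]; the traction grid must be congruent with
#'   the lateral voxel grid of `vol`.
#' @param traction A `traction_field` on the volume's lateral grid.
#' @param substrate An [elastic_substrate()].
#' @param fill Constant padding value used outside the domain when warping.
#' @param interpolation `"tricubic"` (Catmull-Rom, default) or `"trilinear"`.
#' @return The deformed volume, with attribute `displacement` (a
#'   `displacement_field` of the continuum u at every voxel, um).
#' @export
deform_phantom <- function(vol, traction, substrate, fill = NULL,
                           interpolation = c("tricubic", "trilinear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(vol, "ri_volume"), inherits(traction, "traction_field"),
            inherits(substrate, "elastic_substrate"))
  d <- dim(vol$data)
  if (length(traction$x) != d[1] || length(traction$y) != d[2] ||
      !isTRUE(all.equal(unname(traction$pitch), unname(vol$pitch[1:2]))))
    stop("traction grid must be congruent with the volume's lateral voxel grid")
  if (is.null(fill)) fill <- min(vol$data)
  depths <- (seq_len(d[3]) - 1) * vol$pitch[3]
  kern <- sample_greens_kernel(n_lateral = d[1:2], pitch = vol$pitch[1:2],
                               depths = depths, substrate = substrate)
  u <- forward_displacement(traction, kern)    # um, [nx, ny, nz, 3]
  maxu_vox <- max(abs(u$u[, , , 1] / vol$pitch[1]),
                  abs(u$u[, , , 2] / vol$pitch[2]),
                  abs(u$u[, , , 3] / vol$pitch[3]))
  if (maxu_vox > 5)
    warning(sprintf(
      "maximum displacement is %.1f voxels; correlation tracking may fail",
      maxu_vox))
  co <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  xi <- co$i - u$u[cbind(co$i, co$j, co$k, 1)] / vol$pitch[1]
  yi <- co$j - u$u[cbind(co$i, co$j, co$k, 2)] / vol$pitch[2]
  zi <- co$k - u$u[cbind(co$i, co$j, co$k, 3)] / vol$pitch[3]
  interp <- if (interpolation == "tricubic") interp3_cubic
            else interp3_trilinear
  warped <- array(interp(vol$data, xi, yi, zi, fill = fill), dim = d)
  out <- ri_volume(warped, vol$pitch)
  attr(out, "displacement") <- u
  out
}
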
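#' Build the 3D Gaussian high-pass kernel
#'
#' Zero-sum difference-of-(Gaussian, mean) kernel used to isolate bead-scale
#' structure before displacement tracking: a fixed-width isotropic Gaussian
#' (variance 2 voxels^2) normalized to unit sum, minus the flat mean over the
#' anisotropic support, so that the weights sum exactly to zero (DC removal)
#' while the bead-scale passband is preserved. The support half-sizes are the
#' lateral and axial window sizes converted to voxels (rounded half-up).
#'
#' @param w_xy Lateral window half-size in micrometres (default 0.5).
#' @param w_z Axial window half-size in micrometres (default 1).
#' @param voxel_pitch Micrometres per voxel, length 1 or 3.
#' @return 3D array of class `highpass_kernel` with odd support
#'   `(2*wx+1, 2*wy+1, 2*wz+1)`; weights sum to 0 within 1e-12 and the central
#'   weight is positive.
#' @export
#' @examples
#' k <- build_highpass_kernel(0.5, 1, 0.183)
#' sum(k)
build_highpass_kernel <- function(w_xy = 0.5, w_z = 1, voxel_pitch = 0.183) {
  voxel_pitch <- as.numeric(voxel_pitch)
  if (length(voxel_pitch) == 1L) voxel_pitch <- rep(voxel_pitch, 3L)
  w <- floor(c(w_xy, w_xy, w_z) / voxel_pitch + 0.5)  # round half-up
  if (any(w < 1)) stop("window smaller than 1 voxel after pitch conversion")
  i <- -w[1]:w[1]; j <- -w[2]:w[2]; k <- -w[3]:w[3]
  g <- exp(-i^2 / 4) %o% exp(-j^2 / 4) %o% exp(-k^2 / 4)
  K <- g / sum(g) - 1 / length(g)
  K <- K - sum(K) / length(K)    # exact zero sum regardless of rounding
  structure(K, class = c("highpass_kernel", "array"),
            half_width = w, w_xy = w_xy, w_z = w_z)
}

# FFT convolution of a volume with a small centred kernel, reflect padding.
convolve_volume <- function(a, kernel) {
  hw <- (dim(kernel) - 1L) / 2L
  d <- dim(a)
  # reflect pad
  idx <- lapply(1:3, function(ax) {
    n <- d[ax]; h <- hw[ax]
    c(rev(seq_len(min(h, n))), seq_len(n), n + 1 - rev(seq_len(min(h, n))))
  })
  P <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dp <- dim(P)
  kpad <- array(0, dp)
  kpad[seq_len(dim(kernel)[1]), seq_len(dim(kernel)[2]),
       seq_len(dim(kernel)[3])] <- kernel
  kpad <- roll_array(kpad, -hw)     # centre of kernel at index (1,1,1)
  out <- Re(ifftn(fft(P) * fft(kpad)))
  out[hw[1] + seq_len(d[1]), hw[2] + seq_len(d[2]), hw[3] + seq_len(d[3]),
      drop = FALSE]
}

#' Apply the 3D high-pass filter to a volume
#'
#' Linear, shift-equivariant filtering with [build_highpass_kernel()] and
#' reflect padding at the boundary. Constant volumes map to zero.
#'
#' @param vol An [ri_volume()] or 3D array.
#' @param kernel A `highpass_kernel`; built from `w_xy`, `w_z` and the volume
#'   pitch when omitted.
#' @param w_xy,w_z Window half-sizes in micrometres (used when `kernel` is
#'   missing).
#' @return Filtered volume of the same class as the input.
#' @export
highpass_filter <- function(vol, kernel = NULL, w_xy = 0.5, w_z = 1) {
  a <- as_volume_array(vol)
  if (is.null(kernel)) {
    pitch <- if (inherits(vol, "ri_volume")) vol$pitch else
      stop("provide 'kernel' or an 'ri_volume' carrying the voxel pitch")
    kernel <- build_highpass_kernel(w_xy, w_z, pitch)
  }
  out <- convolve_volume(a, unclass(kernel))
  if (inherits(vol, "ri_volume")) ri_volume(out, vol$pitch) else out
}

#' Construct a cell mask
#'
#' Boolean volume marking voxels to exclude from tracking (the cellular
#' region). `cell_mask()` wraps an existing logical array;
#' `mask_box()` builds the rectangular-box mask used in manual delineation;
#' `mask_above_z()` masks everything at depths shallower than a given slice
#' (axial removal of the cellular region).
#'
#' @param mask Logical 3D array (TRUE = masked/cellular voxel).
#' @param provenance One of "manual_box", "threshold", "external".
#' @return Object of class `cell_mask`.
#' @export
cell_mask <- function(mask, provenance = c("external", "manual_box",
                                           "threshold")) {
  provenance <- match.arg(provenance)
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a logical 3D array")
  structure(list(mask = mask, provenance = provenance), class = "cell_mask")
}

#' @rdname cell_mask
#' @param shape Volume shape (3 integers).
#' @param x_range,y_range,z_range Inclusive index ranges of the masked box.
#' @export
mask_box <- function(shape, x_range, y_range, z_range) {
  m <- array(FALSE, shape)
  m[x_range[1]:x_range[2], y_range[1]:y_range[2], z_range[1]:z_range[2]] <- TRUE
  cell_mask(m, "manual_box")
}

#' @rdname cell_mask
#' @param z0 Slices with index `<= z0` are masked (the cell sits above the gel
#'   surface, i.e. at the shallow end of the stack).
#' @export
mask_above_z <- function(shape, z0) {
  m <- array(FALSE, shape)
  if (z0 >= 1) m[, , seq_len(min(z0, shape[3]))] <- TRUE
  cell_mask(m, "manual_box")
}

#' Apply a cell mask to a volume
#'
#' Replaces masked voxels by a fill value. Errors when the mask covers more
#' than 90 percent of the volume (nothing left to track).
#'
#' @param vol An [ri_volume()] or 3D array.
#' @param mask A [cell_mask()] (or logical array).
#' @param fill `"zero"` or `"background"` (median of unmasked voxels).
#' @return Masked volume with attribute `mask_coverage` (fraction masked).
#' @export
apply_mask <- function(vol, mask, fill = c("zero", "background")) {
  fill <- match.arg(fill)
  a <- as_volume_array(vol)
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  if (!identical(dim(a), dim(m))) stop("mask shape does not match the volume")
  cov <- mean(m)
  if (cov > 0.9) stop(sprintf(
    "mask covers %.1f%% of the volume; nothing left to track", 100 * cov))
  fv <- if (fill == "zero") 0 else median(a[!m])
  a[m] <- fv
  out <- if (inherits(vol, "ri_volume")) ri_volume(a, vol$pitch) else a
  attr(out, "mask_coverage") <- cov
  out
}

#' Globally register two volumes by Fourier cross-correlation
#'
#' Estimates a single rigid translation between `ref` and `mov` at subvoxel
#' precision (upsampled cross-correlation) and applies the inverse shift to
#' `mov`. Intended to remove stage drift after high-pass filtering and
#' masking, so that only local bead displacements remain.
#'
#' @param ref,mov Volumes of identical shape.
#' @param upsample Subpixel refinement factor (1/upsample voxel).
#' @param min_quality Minimum normalized correlation at the peak; below this
#'   the volumes are considered non-overlapping and an error is raised.
#' @return List with `shift` (voxels, `mov` relative to `ref`), `quality`,
#'   and `registered` (the inverse-shifted `mov`).
#' @export
global_register <- function(ref, mov, upsample = 100L, min_quality = 0.1) {
  stopifnot_same_shape(ref, mov)
  a <- as_volume_array(ref); b <- as_volume_array(mov)
  res <- subpixel_shift(a, b, upsample = upsample)
  if (!res$valid || res$quality < min_quality)
    stop(sprintf(
      "correlation peak below significance threshold (quality %.3g < %.3g)",
      if (res$valid) res$quality else 0, min_quality))
  registered <- translate_volume(mov, -res$shift, mode = "fourier")
  list(shift = res$shift, quality = res$quality, registered = registered)
}

#' Run the pre-processing chain in the pinned order
#'
#' High-pass filter, then mask, then global registration — the fixed order of
#' the pre-processing pipeline. Both volumes are filtered and masked
#' identically; `mov` is registered onto `ref`.
#'
#' @param ref,mov Volumes ([ri_volume()]).
#' @param mask Optional [cell_mask()].
#' @param w_xy,w_z High-pass window half-sizes (um).
#' @param fill Mask fill rule.
#' @param register Set `FALSE` to skip global registration.
#' @return List with processed `ref`, `mov`, the estimated global `shift` and a
#'   `stages` character vector recording the applied order.
#' @export
prepare_volumes <- function(ref, mov, mask = NULL, w_xy = 0.5, w_z = 1,
                            fill = "zero", register = TRUE) {
  stopifnot_same_shape(ref, mov)
  stages <- character(0)
  kern <- build_highpass_kernel(w_xy, w_z, ref$pitch)
  ref <- highpass_filter(ref, kern)
  mov <- highpass_filter(mov, kern)
  stages <- c(stages, "highpass")
  if (!is.null(mask)) {
    ref <- apply_mask(ref, mask, fill)
    mov <- apply_mask(mov, mask, fill)
    stages <- c(stages, "mask")
  }
  shift <- c(0, 0, 0)
  if (register) {
    reg <- global_register(ref, mov)
    mov <- reg$registered
    shift <- reg$shift
    stages <- c(stages, "register")
  }
  list(ref = ref, mov = mov, shift = shift, stages = stages)
}
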
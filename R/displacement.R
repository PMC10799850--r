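#' Tracking configuration for windowed volume correlation
#'
#' Defaults follow the instrument-scale settings (64^3-voxel subsets on an
#' 11-voxel grid); validation scenes in the package use smaller subsets.
#'
#' @param subset_size Correlation window size in voxels (scalar, per axis).
#' @param grid_spacing Node spacing in voxels.
#' @param upsample Subpixel refinement factor (>= 1; 100 = 0.01 voxel).
#' @param min_valid_fraction Minimum fraction of unmasked voxels per window.
#' @param min_quality Minimum normalized correlation peak per window.
#' @param z_nodes Optional indices of node planes along z to track (e.g. `1:2`
#'   for the two planes nearest the gel surface).
#' @export
tracking_config <- function(subset_size = 64L, grid_spacing = 11L,
                            upsample = 100L, min_valid_fraction = 0.5,
                            min_quality = 0.3, z_nodes = NULL) {
  if (subset_size <= grid_spacing)
    stop("'subset_size' must exceed 'grid_spacing'")
  if (upsample < 1) stop("'upsample' must be >= 1")
  structure(list(subset_size = as.integer(subset_size),
                 grid_spacing = as.integer(grid_spacing),
                 upsample = as.integer(upsample),
                 min_valid_fraction = min_valid_fraction,
                 min_quality = min_quality, z_nodes = z_nodes),
            class = "tracking_config")
}

# Sample the cross-spectrum X on an upsampled lateral/axial offset grid by
# matrix-multiply DFT (one exp-kernel matrix per axis), around `center`.
upsampled_xcorr <- function(X, center, usf, npts) {
  d <- dim(X)
  offs <- ((seq_len(npts) - (npts + 1) / 2)) / usf
  mats <- lapply(seq_along(d), function(ax) {
    f <- fft_freq(d[ax])
    s <- center[ax] + offs
    exp(2i * pi * outer(s, f))        # npts x N
  })
  A <- X
  # contract axis 1, then cycle axes so each contraction hits the first axis
  for (ax in seq_along(d)) {
    da <- dim(A)
    A <- mats[[ax]] %*% matrix(A, da[1], prod(da[-1]))
    dim(A) <- c(npts, da[-1])
    A <- aperm(A, c(seq_along(da)[-1], 1))
  }
  list(cc = Re(A) / length(X), offsets = offs)
}

#' Subpixel shift between two windows by upsampled cross-correlation
#'
#' Full FFT cross-correlation for the integer peak (ties broken toward the
#' smaller shift), then coarse-to-fine local upsampled-correlation refinement
#' via matrix-multiply DFT to `1/upsample` voxel.
#'
#' @param ref_win,mov_win Windows of identical shape (arrays).
#' @param upsample Refinement factor (1 = integer only).
#' @return List: `shift` (voxels; `mov = ref` content moved by `+shift`),
#'   `quality` (normalized correlation at the peak), `valid` (FALSE for flat
#'   windows).
#' @export
subpixel_shift <- function(ref_win, mov_win, upsample = 100L) {
  a <- as_volume_array(ref_win); b <- as_volume_array(mov_win)
  if (!identical(dim(a), dim(b))) stop("windows must have identical shape")
  a <- a - mean(a); b <- b - mean(b)
  ea <- sqrt(sum(a^2)); eb <- sqrt(sum(b^2))
  if (ea == 0 || eb == 0)
    return(list(shift = rep(NA_real_, 3), quality = 0, valid = FALSE))
  d <- dim(a)
  X <- fft(b) * Conj(fft(a))
  cc <- Re(ifftn(X))
  mx <- max(cc)
  cand <- which(cc >= mx - 1e-12 * abs(mx), arr.ind = TRUE)
  # indices -> signed shifts in [-N/2, N/2)
  sh <- sweep(cand - 1L, 2L, d, function(i, n) ((i + n %/% 2) %% n) - n %/% 2)
  ord <- order(rowSums(sh^2), sh[, 1], sh[, 2], sh[, 3])
  shift <- as.numeric(sh[ord[1L], ])
  quality <- mx / (ea * eb)
  if (upsample > 1) {
    usf <- 1
    repeat {
      usf_next <- min(usf * 10, upsample)
      npts <- 2L * as.integer(ceiling(1.5 * usf_next / usf)) + 1L
      up <- upsampled_xcorr(X, shift, usf_next, npts)
      pk <- which(up$cc == max(up$cc), arr.ind = TRUE)[1L, ]
      shift <- shift + up$offsets[pk]
      usf <- usf_next
      if (usf >= upsample) break
    }
  }
  list(shift = shift, quality = quality, valid = TRUE)
}

# Node start offsets (0-based) along one axis: windows [s+1, s+subset]
node_starts <- function(n, subset, spacing) {
  if (n < subset) return(integer(0))
  seq(0L, n - subset, by = spacing)
}

#' Estimate the 3D displacement field between two volumes
#'
#' Windowed FFT cross-correlation with subpixel refinement on a regular node
#' grid. Windows with too few unmasked voxels, a weak correlation peak, zero
#' variance, or an implausibly large shift (more than half the subset) are
#' flagged invalid and filled by inverse-distance interpolation from valid
#' neighbours.
#'
#' @param ref,mov Pre-processed volumes ([ri_volume()]): high-pass filtered,
#'   masked, globally registered.
#' @param cfg A [tracking_config()].
#' @param mask Optional [cell_mask()]; windows overlapping the mask beyond
#'   `min_valid_fraction` are invalidated.
#' @return A `displacement_field`: node positions (um), vectors `u` (um),
#'   validity flags and per-window peak quality. Infilled nodes keep
#'   `valid = FALSE`.
#' @export
estimate_displacement_field <- function(ref, mov, cfg = tracking_config(),
                                        mask = NULL) {
  stopifnot_same_shape(ref, mov)
  a <- as_volume_array(ref); b <- as_volume_array(mov)
  pitch <- if (inherits(ref, "ri_volume")) ref$pitch else rep(1, 3)
  d <- dim(a)
  ss <- cfg$subset_size
  st <- lapply(d, node_starts, subset = ss, spacing = cfg$grid_spacing)
  if (any(lengths(st) == 0L))
    stop("volume smaller than one subset along some axis")
  if (!is.null(cfg$z_nodes)) st[[3]] <- st[[3]][cfg$z_nodes]
  m <- if (is.null(mask)) NULL
       else if (inherits(mask, "cell_mask")) mask$mask else mask
  ni <- length(st[[1]]); nj <- length(st[[2]]); nk <- length(st[[3]])
  u <- array(NA_real_, c(ni, nj, nk, 3))
  valid <- array(FALSE, c(ni, nj, nk))
  quality <- array(NA_real_, c(ni, nj, nk))
  for (k in seq_len(nk)) for (j in seq_len(nj)) for (i in seq_len(ni)) {
    ix <- st[[1]][i] + seq_len(ss); iy <- st[[2]][j] + seq_len(ss)
    iz <- st[[3]][k] + seq_len(ss)
    if (!is.null(m) &&
        mean(!m[ix, iy, iz]) < cfg$min_valid_fraction) next
    res <- subpixel_shift(a[ix, iy, iz], b[ix, iy, iz],
                          upsample = cfg$upsample)
    if (!res$valid || res$quality < cfg$min_quality) {
      quality[i, j, k] <- if (res$valid) res$quality else 0
      next
    }
    if (any(abs(res$shift) >= ss / 2)) { quality[i, j, k] <- res$quality; next }
    u[i, j, k, ] <- res$shift * pitch
    valid[i, j, k] <- TRUE
    quality[i, j, k] <- res$quality
  }
  if (sum(valid) < 4L) stop("fewer than 4 valid windows; cannot form a field")
  # window-centre coordinates, um (0-based voxel indexing -> physical)
  ctr <- function(s) (s + (ss + 1) / 2 - 1)
  pos <- list(ctr(st[[1]]) * pitch[1], ctr(st[[2]]) * pitch[2],
              ctr(st[[3]]) * pitch[3])
  field <- new_displacement_field(pos[[1]], pos[[2]], pos[[3]], u, valid,
                                  quality)
  infill_invalid(field)
}

# Inverse-distance-weighted infill of invalid nodes from valid ones (the
# traction solver needs a complete grid); infilled nodes stay flagged invalid.
infill_invalid <- function(field) {
  if (all(field$valid)) return(field)
  idx <- which(field$valid, arr.ind = TRUE)
  bad <- which(!field$valid, arr.ind = TRUE)
  P <- cbind(field$x[idx[, 1]], field$y[idx[, 2]], field$z[idx[, 3]])
  B <- cbind(field$x[bad[, 1]], field$y[bad[, 2]], field$z[bad[, 3]])
  for (r in seq_len(nrow(bad))) {
    d2 <- colSums((t(P) - B[r, ])^2)
    w <- 1 / pmax(d2, .Machine$double.eps)
    w <- w / sum(w)
    for (c in 1:3)
      field$u[bad[r, 1], bad[r, 2], bad[r, 3], c] <-
        sum(w * field$u[cbind(idx, c)])
  }
  field
}

#' Displacement-field error statistics
#'
#' Per-axis RMSE, mean and standard deviation of a measured field against an
#' expected field or constant vector, over valid nodes only.
#'
#' @param field A `displacement_field`.
#' @param expected A congruent `displacement_field`, or a length-3 constant
#'   vector (um).
#' @return Data frame with one row per axis: `mean`, `sd`, `rmse`, `bias`,
#'   and the node count `n`.
#' @export
field_stats <- function(field, expected = c(0, 0, 0)) {
  stopifnot(inherits(field, "displacement_field"))
  v <- field$valid
  if (!any(v)) stop("no valid nodes")
  exp_u <- if (inherits(expected, "displacement_field")) {
    if (!identical(dim(expected$u), dim(field$u)))
      stop("grids are not congruent")
    expected$u
  } else {
    if (length(expected) != 3L) stop("'expected' must be length 3 or a field")
    array(rep(expected, each = length(v)), c(dim(v), 3))
  }
  out <- data.frame(axis = c("x", "y", "z"), mean = NA_real_, sd = NA_real_,
                    rmse = NA_real_, bias = NA_real_, n = sum(v))
  for (c in 1:3) {
    meas <- field$u[, , , c, drop = FALSE][v]
    ref <- exp_u[, , , c, drop = FALSE][v]
    err <- meas - ref
    out$mean[c] <- mean(meas)
    out$sd[c] <- if (length(meas) > 1) sd(meas) else 0
    out$rmse[c] <- sqrt(mean(err^2))
    out$bias[c] <- mean(err)
  }
  out
}
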
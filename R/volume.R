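#' Construct a 3D scalar volume
#'
#' The basic image container of the package: a 3D numeric array (refractive
#' index contrast or intensity) together with its voxel pitch in micrometres.
#' Axis order is `[x, y, z]`; slice `z = 1` is the gel surface and the z index
#' increases with depth into the substrate.
#'
#' @param data 3D numeric array.
#' @param pitch Voxel pitch in micrometres, length 1 (isotropic) or 3
#'   `(x, y, z)`.
#' @return An object of class `ri_volume`.
#' @export
#' @examples
#' v <- ri_volume(array(0, c(8, 8, 4)), pitch = 0.183)
#' dim(v)
ri_volume <- function(data, pitch) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("'pitch' must be 1 or 3 positive finite values (micrometres)")
  structure(list(data = data, pitch = setNames(pitch, c("x", "y", "z"))),
            class = "ri_volume")
}

#' @export
dim.ri_volume <- function(x) dim(x$data)

#' @export
print.ri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ri_volume> %d x %d x %d voxels, pitch %.4g x %.4g x %.4g um\n",
              d[1], d[2], d[3], x$pitch[1], x$pitch[2], x$pitch[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

as_volume_array <- function(vol) {
  if (inherits(vol, "ri_volume")) vol$data
  else if (is.array(vol) && length(dim(vol)) == 3L) vol
  else stop("expected an 'ri_volume' or a 3D array")
}

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(as_volume_array(a)), dim(as_volume_array(b))))
    stop("volumes must have identical dimensions")
}

## ---- small FFT helpers ----------------------------------------------------

ifftn <- function(x) fft(x, inverse = TRUE) / length(x)

# Signed FFT frequencies k/N for axis length n (cycles per sample).
fft_freq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

# Circularly roll an array by integer shifts (content moves by +shift).
roll_array <- function(a, shift) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(ax) {
    s <- shift[ax] %% d[ax]
    if (s == 0) seq_len(d[ax]) else c((d[ax] - s + 1):d[ax], 1:(d[ax] - s))
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Exact band-limited subvoxel shift via Fourier phase ramps
# (content moves by +shift voxels; circular boundary).
fourier_shift_array <- function(a, shift) {
  d <- dim(a)
  F <- fft(a)
  for (ax in seq_along(d)) {
    if (shift[ax] == 0) next
    ph <- exp(-2i * pi * fft_freq(d[ax]) * shift[ax])
    # Nyquist bin of an even-length axis must stay real for a real signal
    if (d[ax] %% 2L == 0L) ph[d[ax] / 2L + 1L] <- cos(2 * pi * 0.5 * shift[ax])
    shp <- rep(1L, length(d)); shp[ax] <- d[ax]
    F <- F * array(rep(ph, each = prod(d[seq_len(ax - 1L)])), dim = d)
  }
  Re(ifftn(F))
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## ---- trilinear interpolation ----------------------------------------------

# Sample a 3D array at fractional 1-based voxel coordinates; constant padding
# with `fill` outside the domain. xi/yi/zi are equal-length vectors.
interp3_trilinear <- function(a, xi, yi, zi, fill = 0) {
  d <- dim(a)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0;   fy <- yi - y0;   fz <- zi - z0
  out <- numeric(length(xi))
  get8 <- function(ix, iy, iz) {
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    v <- rep(fill, length(ix))
    if (any(ok)) v[ok] <- a[cbind(ix[ok], iy[ok], iz[ok])]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    nz <- w != 0
    if (any(nz))
      out[nz] <- out[nz] +
        w[nz] * get8(x0[nz] + dx, y0[nz] + dy, z0[nz] + dz)
  }
  out
}

# Catmull-Rom weights for the 4-tap stencil at offsets -1, 0, 1, 2
catmull_rom_w <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  list(0.5 * (-t3 + 2 * t2 - t),
       0.5 * (3 * t3 - 5 * t2 + 2),
       0.5 * (-3 * t3 + 4 * t2 + t),
       0.5 * (t3 - t2))
}

# Separable tricubic (Catmull-Rom) interpolation at fractional 1-based voxel
# coordinates; constant padding outside the domain.
interp3_cubic <- function(a, xi, yi, zi, fill = 0) {
  d <- dim(a)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  wx <- catmull_rom_w(xi - x0)
  wy <- catmull_rom_w(yi - y0)
  wz <- catmull_rom_w(zi - z0)
  out <- numeric(length(xi))
  for (dz in -1:2) {
    iz <- z0 + dz
    okz <- iz >= 1 & iz <= d[3]
    wzv <- wz[[dz + 2]]
    for (dy in -1:2) {
      iy <- y0 + dy
      oky <- okz & iy >= 1 & iy <= d[2]
      wyz <- wzv * wy[[dy + 2]]
      for (dx in -1:2) {
        ix <- x0 + dx
        ok <- oky & ix >= 1 & ix <= d[1]
        v <- rep(fill, length(xi))
        if (any(ok)) v[ok] <- a[cbind(ix[ok], iy[ok], iz[ok])]
        out <- out + wyz * wx[[dx + 2]] * v
      }
    }
  }
  out
}
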
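# Independent oracles used by the tests.

# Exact 1D total-variation denoiser (direct non-iterative algorithm),
# independent of the package's dual-projection prox.
tv1d_exact <- function(y, lam) {
  N <- length(y)
  if (N == 0L) return(y)
  if (N == 1L || lam <= 0) return(y)
  x <- numeric(N)
  k <- k0 <- km <- kp <- 1L
  vmin <- y[1] - lam; vmax <- y[1] + lam
  umin <- lam; umax <- -lam
  repeat {
    if (k == N) {
      if (umin < 0) {
        x[k0:km] <- vmin
        k <- k0 <- km <- km + 1L
        vmin <- y[k]
        umin <- lam
        umax <- y[k] + lam - vmax
      } else if (umax > 0) {
        x[k0:kp] <- vmax
        k <- k0 <- kp <- kp + 1L
        vmax <- y[k]
        umax <- -lam
        umin <- y[k] - lam - vmin
      } else {
        x[k0:N] <- vmin + umin / (k - k0 + 1)
        return(x)
      }
      if (k > N) return(x)
    }
    if (k < N && y[k + 1] + umin < vmin - lam) {          # negative jump
      x[k0:km] <- vmin
      k <- k0 <- km <- kp <- km + 1L
      vmin <- y[k]; vmax <- y[k] + 2 * lam
      umin <- lam; umax <- -lam
    } else if (k < N && y[k + 1] + umax > vmax + lam) {   # positive jump
      x[k0:kp] <- vmax
      k <- k0 <- km <- kp <- kp + 1L
      vmin <- y[k] - 2 * lam; vmax <- y[k]
      umin <- lam; umax <- -lam
    } else if (k < N) {                                    # no jump
      k <- k + 1L
      umin <- umin + y[k] - vmin
      umax <- umax + y[k] - vmax
      if (umin >= lam) {
        vmin <- vmin + (umin - lam) / (k - k0 + 1)
        umin <- lam
        km <- k
      }
      if (umax <= -lam) {
        vmax <- vmax + (umax + lam) / (k - k0 + 1)
        umax <- -lam
        kp <- k
      }
    }
  }
}

# 1D TV objective (for oracle cross-checks)
tv1d_objective <- function(x, y, lam) 0.5 * sum((x - y)^2) + lam * sum(abs(diff(x)))

# Direct double-sum evaluation of the elastic forward operator (aperiodic),
# independent of the package's FFT path. Uses the same singular-cell rule.
direct_forward_oracle <- function(traction, substrate, depths, pitch) {
  nx <- length(traction$x); ny <- length(traction$y)
  area <- pitch[1] * pitch[2] * 1e-12 * 1e6   # Pa on a cell -> um
  u <- array(0, c(nx, ny, length(depths), 3))
  avg <- ritfm:::singular_cell_average(pitch * 1e-6, substrate)
  G_avg <- matrix(c(avg$xx, avg$yx, avg$zx, avg$xy, avg$yy, avg$zy,
                    avg$xz, avg$yz, avg$zz), 3, 3)
  for (d in seq_along(depths)) for (i in seq_len(nx)) for (j in seq_len(ny)) {
    acc <- c(0, 0, 0)
    for (ii in seq_len(nx)) for (jj in seq_len(ny)) {
      dx <- traction$x[i] - traction$x[ii]
      dy <- traction$y[j] - traction$y[jj]
      G <- if (dx == 0 && dy == 0 && depths[d] == 0) G_avg
           else greens_tensor(dx, dy, depths[d], substrate)
      acc <- acc + G %*% c(traction$tx[ii, jj], traction$ty[ii, jj],
                           traction$tz[ii, jj]) * area
    }
    u[i, j, d, ] <- acc
  }
  u
}

# Centroid of a volume along one axis (for subvoxel-shift checks)
axis_centroid <- function(a, axis = 1) {
  p <- apply(a, axis, sum)
  sum(seq_along(p) * p) / sum(p)
}

# A small shared bead phantom (memoized across test files)
.shared <- new.env()
shared_phantom <- function() {
  if (is.null(.shared$phantom))
    .shared$phantom <- make_bead_phantom(
      phantom_spec(c(48L, 48L, 48L), 0.183, seed = 42L))
  .shared$phantom
}
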
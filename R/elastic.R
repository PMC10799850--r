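#' Linear elastic substrate parameters
#'
#' @param E Young's modulus in Pa (> 0); typical hydrogels here are 11 kPa
#'   (adherent cells) and 1.2 kPa (T cells).
#' @param nu Poisson's ratio in `[0, 0.5]`; polyacrylamide is close to the
#'   incompressible limit 0.5.
#' @return Object of class `elastic_substrate`. The gel surface is the plane
#'   z = 0 with z increasing into the gel.
#' @export
elastic_substrate <- function(E, nu = 0.5) {
  if (!is.numeric(E) || E <= 0) stop("Young's modulus E must be > 0")
  if (nu < 0 || nu > 0.5) stop("Poisson's ratio nu must be in [0, 0.5]")
  structure(list(E = E, nu = nu), class = "elastic_substrate")
}

# The nine Boussinesq-Cerruti components, vectorized over x, y (m) at a single
# depth z (m, >= 0). Returns m/N. G[alpha, beta] = displacement along alpha at
# (x,y,z) per unit point force along beta applied at the surface origin.
greens_components <- function(x, y, z, substrate) {
  E <- substrate$E; nu <- substrate$nu
  C <- (1 + nu) / (2 * pi * E)
  k <- 1 - 2 * nu
  r <- sqrt(x^2 + y^2 + z^2)
  t <- r + z
  list(
    xx = C * (1 / r + x^2 / r^3 + k * (1 / t - x^2 / (r * t^2))),
    xy = C * (x * y / r^3 - k * x * y / (r * t^2)),
    xz = C * (x * z / r^3 - k * x / (r * t)),
    yx = C * (x * y / r^3 - k * x * y / (r * t^2)),
    yy = C * (1 / r + y^2 / r^3 + k * (1 / t - y^2 / (r * t^2))),
    yz = C * (y * z / r^3 - k * y / (r * t)),
    zx = C * (x * z / r^3 + k * x / (r * t)),
    zy = C * (y * z / r^3 + k * y / (r * t)),
    zz = C * (z^2 / r^3 + 2 * (1 - nu) / r)
  )
}

#' Evaluate the half-space Green's tensor at a point
#'
#' Displacement Green's tensor of a linear elastic half-space loaded by a point
#' force on its free surface (Boussinesq solution for the normal component,
#' Cerruti for the tangential ones), evaluated at lateral offset `(x, y)` and
#' depth `z` below the surface. At the surface (z = 0) the tensor reduces to
#' the familiar 2D traction-force-microscopy kernel: with nu = 0.5 the
#' shear-normal coupling components vanish identically and
#' `G_zz = 3 / (4 pi E rho)`.
#'
#' @param x,y Lateral offsets from the load point, micrometres.
#' @param z Depth below the surface, micrometres (>= 0).
#' @param substrate An [elastic_substrate()].
#' @return 3x3 matrix in m/N, rows = displacement component (x, y, z),
#'   columns = force component.
#' @export
#' @examples
#' G <- greens_tensor(1, 0, 0, elastic_substrate(E = 1000, nu = 0.5))
#' G["z", "z"] # 3/(4*pi*1000*1e-6) ~ 238.73 m/N
greens_tensor <- function(x, y, z, substrate) {
  stopifnot(inherits(substrate, "elastic_substrate"))
  if (z < 0) stop("depth z must be >= 0")
  if (x == 0 && y == 0 && z == 0)
    stop("Green's tensor is singular at the origin; ",
         "use sample_greens_kernel() for a regularized cell value")
  g <- greens_components(x * 1e-6, y * 1e-6, z * 1e-6, substrate)
  matrix(c(g$xx, g$yx, g$zx, g$xy, g$yy, g$zy, g$xz, g$yz, g$zz), 3, 3,
         dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
}

# Midpoint-quadrature average of the surface-plane tensor over the grid cell
# containing the singular origin (the 1/rho singularity is integrable).
singular_cell_average <- function(pitch_m, substrate, m = 16L) {
  hx <- pitch_m[1]; hy <- pitch_m[2]
  xs <- (seq_len(m) - (m + 1) / 2) / m * hx
  ys <- (seq_len(m) - (m + 1) / 2) / m * hy
  X <- matrix(xs, m, m); Y <- matrix(ys, m, m, byrow = TRUE)
  g <- greens_components(X, Y, 0, substrate)
  lapply(g, mean)
}

#' Sample the Green's tensor on a convolution grid
#'
#' Samples all nine tensor components on a zero-padded lateral offset grid
#' (padding = one full domain per axis, preventing wraparound in FFT
#' convolution) at each requested depth plane, and pre-computes their FFTs.
#' The singular cell at zero lateral offset and zero depth is replaced by the
#' quadrature average of the tensor over that grid cell; the treatment is
#' recorded in the returned object.
#'
#' @param n_lateral Traction-grid size, length 2 `(nx, ny)`.
#' @param pitch Grid pitch in micrometres, length 1 or 2.
#' @param depths Depth planes in micrometres (>= 0); must be non-empty.
#' @param substrate An [elastic_substrate()].
#' @param singular_subgrid Midpoint-quadrature subdivisions for the singular
#'   cell.
#' @return Object of class `greens_kernel`. The stored spectra convert Pa on
#'   grid cells directly to micrometres of displacement.
#' @export
sample_greens_kernel <- function(n_lateral, pitch, depths, substrate,
                                 singular_subgrid = 16L) {
  stopifnot(inherits(substrate, "elastic_substrate"))
  if (length(depths) < 1L) stop("'depths' must contain at least one plane")
  if (any(depths < 0)) stop("'depths' must be >= 0")
  pitch <- as.numeric(pitch)
  if (length(pitch) == 1L) pitch <- rep(pitch, 2L)
  if (any(pitch <= 0)) stop("grid pitch must be > 0")
  nx <- n_lateral[1]; ny <- n_lateral[2]
  Px <- 2L * nx; Py <- 2L * ny
  pitch_m <- pitch * 1e-6
  # offsets in wrap-around (circulant) arrangement: index 1 <-> zero offset
  ox <- (((seq_len(Px) - 1) + Px / 2) %% Px - Px / 2) * pitch_m[1]
  oy <- (((seq_len(Py) - 1) + Py / 2) %% Py - Py / 2) * pitch_m[2]
  X <- matrix(ox, Px, Py)
  Y <- matrix(oy, Px, Py, byrow = TRUE)
  comp_names <- c("xx", "xy", "xz", "yx", "yy", "yz", "zx", "zy", "zz")
  nd <- length(depths)
  # cells -> displacement scale: G [m/N] * traction [Pa] * cell area [m^2]
  # gives metres; report micrometres
  scale <- pitch_m[1] * pitch_m[2] * 1e6
  Khat <- array(complex(real = 0), dim = c(Px, Py, nd, 3, 3))
  singular <- NULL
  for (d in seq_len(nd)) {
    z <- depths[d] * 1e-6
    g <- greens_components(X, Y, z, substrate)
    if (z == 0) {
      avg <- singular_cell_average(pitch_m, substrate, m = singular_subgrid)
      for (nm in comp_names) g[[nm]][1, 1] <- avg[[nm]]
      singular <- sprintf("midpoint quadrature average, %d^2 subgrid",
                          singular_subgrid)
    }
    for (a in 1:3) for (b in 1:3) {
      nm <- comp_names[(a - 1) * 3 + b]
      Khat[, , d, a, b] <- fft(g[[nm]] * scale)
    }
  }
  structure(list(nx = nx, ny = ny, Px = Px, Py = Py, pitch = pitch,
                 depths = depths, substrate = substrate, Khat = Khat,
                 singular_cell = if (is.null(singular)) "none (all depths > 0)"
                                 else singular),
            class = "greens_kernel")
}

#' @export
print.greens_kernel <- function(x, ...) {
  cat(sprintf(
    "<greens_kernel> %d x %d lateral grid (pitch %.3g x %.3g um), %d depth plane(s)\n",
    x$nx, x$ny, x$pitch[1], x$pitch[2], length(x$depths)))
  cat(sprintf("  E = %g Pa, nu = %g; singular cell: %s\n",
              x$substrate$E, x$substrate$nu, x$singular_cell))
  invisible(x)
}

new_displacement_field <- function(x, y, z, u, valid = NULL, quality = NULL) {
  dims <- c(length(x), length(y), length(z))
  stopifnot(identical(dim(u), c(dims, 3L)))
  if (is.null(valid)) valid <- array(TRUE, dims)
  if (is.null(quality)) quality <- array(NA_real_, dims)
  structure(list(x = x, y = y, z = z, u = u, valid = valid, quality = quality),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d x %d x %d nodes, %d/%d valid\n",
              length(x$x), length(x$y), length(x$z), sum(x$valid),
              length(x$valid)))
  m <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("  max |u| = %.4g um\n", suppressWarnings(max(m[x$valid]))))
  invisible(x)
}

pad2 <- function(m, Px, Py) {
  out <- matrix(0, Px, Py)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

#' Forward elastic operator: traction to displacement
#'
#' Computes u(r) = (G x T)(r) at every kernel depth plane by FFT convolution
#' of each tensor component with each traction component (zero-padded by a
#' full domain per axis, so the result equals aperiodic summation).
#'
#' @param traction A `traction_field` on the kernel's lateral grid.
#' @param kernel A [sample_greens_kernel()] result.
#' @return A `displacement_field` (um) on the traction grid, one z slab per
#'   kernel depth.
#' @export
forward_displacement <- function(traction, kernel) {
  stopifnot(inherits(traction, "traction_field"),
            inherits(kernel, "greens_kernel"))
  if (length(traction$x) != kernel$nx || length(traction$y) != kernel$ny)
    stop("traction grid does not match the kernel grid")
  nx <- kernel$nx; ny <- kernel$ny
  FT <- list(fft(pad2(traction$tx, kernel$Px, kernel$Py)),
             fft(pad2(traction$ty, kernel$Px, kernel$Py)),
             fft(pad2(traction$tz, kernel$Px, kernel$Py)))
  nd <- length(kernel$depths)
  u <- array(0, c(nx, ny, nd, 3))
  for (d in seq_len(nd)) for (a in 1:3) {
    acc <- kernel$Khat[, , d, a, 1] * FT[[1]] +
           kernel$Khat[, , d, a, 2] * FT[[2]] +
           kernel$Khat[, , d, a, 3] * FT[[3]]
    u[, , d, a] <- Re(ifftn(acc))[seq_len(nx), seq_len(ny)]
  }
  new_displacement_field(traction$x, traction$y, kernel$depths, u)
}

#' Adjoint elastic operator: displacement to traction space
#'
#' Transpose of [forward_displacement()] (cross-correlation with the kernel,
#' summed over displacement components and depth planes). Satisfies the
#' inner-product identity `<G T, u> = <T, G^t u>` to machine precision.
#'
#' @param field A `displacement_field` on the kernel grid (um).
#' @param kernel A [sample_greens_kernel()] result.
#' @return A `traction_field`-shaped object (arbitrary units).
#' @export
adjoint_displacement <- function(field, kernel) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(kernel, "greens_kernel"))
  if (length(field$x) != kernel$nx || length(field$y) != kernel$ny ||
      length(field$z) != length(kernel$depths))
    stop("displacement grid does not match the kernel grid")
  nx <- kernel$nx; ny <- kernel$ny
  nd <- length(kernel$depths)
  FU <- vector("list", 3L * nd)
  out <- vector("list", 3L)
  for (b in 1:3) {
    acc <- matrix(complex(real = 0), kernel$Px, kernel$Py)
    for (d in seq_len(nd)) for (a in 1:3) {
      idx <- (d - 1) * 3 + a
      if (is.null(FU[[idx]]))
        FU[[idx]] <- fft(pad2(field$u[, , d, a], kernel$Px, kernel$Py))
      acc <- acc + Conj(kernel$Khat[, , d, a, b]) * FU[[idx]]
    }
    out[[b]] <- Re(ifftn(acc))[seq_len(nx), seq_len(ny)]
  }
  grid <- list(x = field$x, y = field$y, pitch = kernel$pitch)
  new_traction_field(out[[1]], out[[2]], out[[3]], grid)
}
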
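#' Dry-mass conversion parameters
#'
#' @param alpha_ri Refraction increment dRI/dc in mL/g (default 0.185, the
#'   protein value).
#' @param n_medium Background (medium) refractive index; required for
#'   absolute-RI volumes, 0 for volumes already expressed as RI excess.
#' @param gravity Gravitational acceleration, m/s^2.
#' @export
dry_mass_params <- function(alpha_ri = 0.185, n_medium = 1.337,
                            gravity = 9.8) {
  if (alpha_ri <= 0) stop("'alpha_ri' must be > 0")
  structure(list(alpha_ri = alpha_ri, n_medium = n_medium, gravity = gravity),
            class = "dry_mass_params")
}

#' Convert a refractive-index volume to dry-mass density
#'
#' `c = (n - n_medium) / alpha` per voxel, in g/mL. Negative densities
#' (noise below the background) are clamped to zero; the clamped fraction is
#' recorded as an attribute.
#'
#' @param vol RI volume ([ri_volume()]).
#' @param params A [dry_mass_params()].
#' @return Density volume (g/mL) with attribute `fraction_clamped`.
#' @export
#' @examples
#' v <- ri_volume(array(1.337 + 0.0185, c(4, 4, 4)), 0.2)
#' ri_to_density(v, dry_mass_params())$data[1, 1, 1]  # 0.1 g/mL
ri_to_density <- function(vol, params = dry_mass_params()) {
  stopifnot(inherits(params, "dry_mass_params"))
  a <- as_volume_array(vol)
  dens <- (a - params$n_medium) / params$alpha_ri
  clamped <- mean(dens < 0)
  dens[dens < 0] <- 0
  out <- if (inherits(vol, "ri_volume")) ri_volume(dens, vol$pitch) else dens
  attr(out, "fraction_clamped") <- clamped
  out
}

#' Project a density volume to a surface dry-mass density map
#'
#' Axial integral of the density per lateral pixel:
#' 1 g/mL x um = 1000 fg/um^2.
#'
#' @param density Density volume in g/mL ([ri_volume()]).
#' @return Object of class `surface_density_map`: matrix in fg/um^2 plus the
#'   lateral pitch.
#' @export
surface_density_map <- function(density) {
  stopifnot(inherits(density, "ri_volume"))
  map <- apply(density$data, c(1, 2), sum) * density$pitch[3] * 1000
  structure(list(map = map, pitch = density$pitch[1:2]),
            class = "surface_density_map")
}

#' Gravitational pressure of the projected dry mass
#'
#' `P = sigma * g`, converting fg/um^2 to kg/m^2 (factor 1e-6). Realistic
#' surface densities of 1-100 fg/um^2 give pressures below a millipascal,
#' around five orders of magnitude below 100-Pa-scale cellular tractions.
#'
#' @param map A [surface_density_map()] or numeric (fg/um^2).
#' @param params A [dry_mass_params()].
#' @return Pressure in Pa, same shape as the input map.
#' @export
#' @examples
#' weight_pressure(20.45)  # ~2.0e-4 Pa
weight_pressure <- function(map, params = dry_mass_params()) {
  sigma <- if (inherits(map, "surface_density_map")) map$map else map
  sigma * 1e-6 * params$gravity
}

#' Summary statistics of a traction field
#'
#' Mean, standard deviation, and maximum of the shear magnitude
#' `sqrt(Tx^2 + Ty^2)` and of the normal component `Tz`, with histograms
#' (Freedman-Diaconis binning). Optionally restricted to nodes whose
#' respective magnitude exceeds a significance threshold.
#'
#' @param traction A `traction_field` (Pa).
#' @param threshold Optional magnitude threshold in Pa.
#' @return List with `shear` and `normal` summaries (`mean`, `sd`, `max`,
#'   `n`, `histogram`).
#' @export
traction_stats <- function(traction, threshold = NULL) {
  stopifnot(inherits(traction, "traction_field"))
  if (length(traction$tx) == 0) stop("empty traction field")
  shear <- sqrt(traction$tx^2 + traction$ty^2)
  tz <- traction$tz
  summarize <- function(v) {
    if (!is.null(threshold)) v <- v[abs(v) >= threshold]
    if (length(v) == 0)
      return(list(mean = NA_real_, sd = NA_real_, max = NA_real_, n = 0L,
                  histogram = NULL))
    h <- if (length(unique(v)) > 1) graphics::hist(v, breaks = "FD",
                                                   plot = FALSE) else NULL
    list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
         max = max(abs(v)) * sign(v[which.max(abs(v))]),
         n = length(v), histogram = h)
  }
  list(shear = summarize(as.vector(shear)),
       normal = summarize(as.vector(tz)))
}

#' Differential traction between consecutive frames
#'
#' `dT_j = T_j - T_{j-1}`, with the first-frame convention `T_0 = 0` (so
#' `dT_1 = T_1`). Differences telescope: the sum of all increments equals the
#' final field.
#'
#' @param t_now Traction field at frame j.
#' @param t_prev Traction field at frame j-1, or `NULL` for the first frame.
#' @return A `traction_field` of nodewise differences.
#' @export
differential_traction <- function(t_now, t_prev = NULL) {
  stopifnot(inherits(t_now, "traction_field"))
  if (is.null(t_prev)) return(t_now)
  stopifnot(inherits(t_prev, "traction_field"))
  if (!identical(dim(t_now$tx), dim(t_prev$tx)))
    stop("traction grids are not congruent")
  new_traction_field(t_now$tx - t_prev$tx, t_now$ty - t_prev$ty,
                     t_now$tz - t_prev$tz,
                     list(x = t_now$x, y = t_now$y, pitch = t_now$pitch))
}

#' Kymograph of a time series of 2D maps
#'
#' Reduces each map to a 1D profile along the chosen axis (maximum or mean
#' across the other lateral axis) and stacks the profiles over time.
#'
#' @param maps List of congruent 2D matrices (one per time point, >= 2).
#' @param axis Profile axis, `"x"` (rows) or `"y"` (columns).
#' @param reduce `"max"` or `"mean"` across the other axis.
#' @return Matrix of size position x time.
#' @export
kymograph <- function(maps, axis = c("x", "y"), reduce = c("max", "mean")) {
  axis <- match.arg(axis)
  reduce <- match.arg(reduce)
  if (!is.list(maps) || length(maps) < 2L)
    stop("need at least 2 time points")
  d0 <- dim(maps[[1]])
  fn <- if (reduce == "max") max else mean
  prof <- function(m) {
    if (!identical(dim(m), d0)) stop("maps are not congruent across time")
    apply(m, if (axis == "x") 1 else 2, fn)
  }
  vapply(maps, prof, numeric(if (axis == "x") d0[1] else d0[2]))
}

#' 3D morphology parameters of a cell body
#'
#' Maximum cell thickness (axial extent of supra-threshold voxels per lateral
#' pixel) and mean surface dry-mass density over the cell footprint.
#'
#' @param density Density volume in g/mL ([ri_volume()]).
#' @param mask Optional [cell_mask()] defining the cell support; otherwise a
#'   density threshold is used.
#' @param threshold Density threshold in g/mL defining the support (default
#'   0.02).
#' @return List: `max_thickness_um`, `mean_surface_density_fg_um2`,
#'   `footprint_px`.
#' @export
morphology_params <- function(density, mask = NULL, threshold = 0.02) {
  stopifnot(inherits(density, "ri_volume"))
  supp <- if (!is.null(mask)) {
    m <- if (inherits(mask, "cell_mask")) mask$mask else mask
    if (!identical(dim(m), dim(density$data)))
      stop("mask shape does not match the volume")
    m
  } else density$data > threshold
  if (!any(supp)) stop("empty cell support")
  d <- dim(supp)
  thick <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) thick <- thick + supp[, , k]
  # axial extent: first-to-last supra-threshold slice per pixel
  kfirst <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  kfirst[!supp] <- NA
  extent <- apply(kfirst, c(1, 2), function(v) {
    if (all(is.na(v))) 0 else diff(range(v, na.rm = TRUE)) + 1
  })
  sdm <- surface_density_map(density)
  foot <- extent > 0
  list(max_thickness_um = unname(max(extent) * density$pitch[3]),
       mean_surface_density_fg_um2 = mean(sdm$map[foot]),
       footprint_px = sum(foot))
}
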
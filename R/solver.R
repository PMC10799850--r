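#' FISTA configuration
#'
#' Parameters of the monotone TV-FISTA engine. The defaults are the
#' traction-inversion settings (step size 0.01, TV weight 0.02, 200 inner /
#' 240 outer iterations, monotone). The high-level solvers normalize the data
#' to unit scale and the forward operator so that the configured step size is
#' the critical step, making `step_size` and `tv_weight` dimensionless.
#'
#' @param step_size Gradient step alpha (> 0), relative to 1/L of the
#'   normalized operator.
#' @param tv_weight Total-variation weight tau (>= 0).
#' @param inner_iterations Dual projection steps of each TV proximal map.
#' @param outer_iterations Gradient (FISTA) steps.
#' @param monotone Use the monotone FISTA variant (objective never increases).
#' @param nonnegativity Clamp the iterates at zero (used for refractive-index
#'   deconvolution, not for tractions).
#' @export
fista_config <- function(step_size = 0.01, tv_weight = 0.02,
                         inner_iterations = 200L, outer_iterations = 240L,
                         monotone = TRUE, nonnegativity = FALSE) {
  if (step_size <= 0) stop("'step_size' must be > 0")
  if (tv_weight < 0) stop("'tv_weight' must be >= 0")
  if (inner_iterations < 1 || outer_iterations < 1)
    stop("iteration counts must be >= 1")
  structure(list(step_size = step_size, tv_weight = tv_weight,
                 inner_iterations = as.integer(inner_iterations),
                 outer_iterations = as.integer(outer_iterations),
                 monotone = isTRUE(monotone),
                 nonnegativity = isTRUE(nonnegativity)),
            class = "fista_config")
}

# forward difference along axis `ax` (last slice zero)
diff_fwd <- function(x, ax) {
  d <- dim(x); n <- d[ax]
  idx1 <- lapply(d, seq_len); idx0 <- idx1
  idx1[[ax]] <- c(2:n, n); idx0[[ax]] <- c(seq_len(n - 1), n)
  out <- do.call(`[`, c(list(x), idx1)) - do.call(`[`, c(list(x), idx0))
  array(out, d)
}

# adjoint of diff_fwd: (D^t p)_i = p_{i-1} - p_i, with the convention that
# the last dual slice is ignored (it multiplies a zero difference)
diff_adj <- function(p, ax) {
  d <- dim(p); n <- d[ax]
  idx <- lapply(d, seq_len)
  idxl <- idx; idxl[[ax]] <- n
  pl <- p
  pl <- do.call(`[<-`, c(list(pl), idxl, list(value = 0)))
  shifted <- array(0, d)
  idxs <- idx; idxs[[ax]] <- 2:n
  idxp <- idx; idxp[[ax]] <- seq_len(n - 1)
  shifted <- do.call(`[<-`, c(list(shifted), idxs,
                              list(value = do.call(`[`, c(list(pl), idxp)))))
  shifted - pl
}

#' Total variation of an array
#'
#' Isotropic TV with forward differences over all array dimensions.
#'
#' @param x Numeric array (2D or 3D).
#' @return Scalar TV value.
#' @export
tv_norm <- function(x) {
  nd <- length(dim(x))
  s <- 0
  g2 <- 0
  for (ax in seq_len(nd)) g2 <- g2 + diff_fwd(x, ax)^2
  sum(sqrt(g2))
}

#' Proximal map of the total-variation seminorm
#'
#' Approximate solution of `argmin_u 0.5*||u - x||^2 + weight * TV(u)` via
#' fast gradient projection on the dual problem (isotropic TV, forward
#' differences). `weight = 0` returns the input unchanged; constant inputs are
#' fixed points for any weight.
#'
#' @param x Numeric array (2D or 3D).
#' @param weight TV weight (>= 0).
#' @param inner_iterations Dual projection iterations.
#' @return Denoised array of the same shape.
#' @export
tv_prox <- function(x, weight, inner_iterations = 50L) {
  if (weight < 0) stop("'weight' must be >= 0")
  if (weight == 0) return(x)
  if (any(dim(x) < 2L)) stop("tv_prox needs at least 2 samples per dimension")
  if (length(dim(x)) == 2L) return(tv_prox_2d(x, weight, inner_iterations))
  d <- dim(x); nd <- length(d)
  p <- q <- lapply(seq_len(nd), function(a) array(0, d))
  t_k <- 1
  step <- 1 / (4 * nd * weight)
  for (it in seq_len(inner_iterations)) {
    # gradient of the dual objective at the extrapolated point q
    div_q <- Reduce(`+`, lapply(seq_len(nd), function(a) diff_adj(q[[a]], a)))
    r <- x - weight * div_q
    p_new <- lapply(seq_len(nd), function(a) q[[a]] + step * diff_fwd(r, a))
    nrm <- sqrt(Reduce(`+`, lapply(p_new, function(m) m^2)))
    scl <- 1 / pmax(1, nrm)
    p_new <- lapply(p_new, function(m) m * scl)
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    q <- lapply(seq_len(nd), function(a)
      p_new[[a]] + ((t_k - 1) / t_next) * (p_new[[a]] - p[[a]]))
    p <- p_new
    t_k <- t_next
  }
  div_p <- Reduce(`+`, lapply(seq_len(nd), function(a) diff_adj(p[[a]], a)))
  x - weight * div_p
}

#' Monotone TV-FISTA solver
#'
#' Minimizes `0.5*||op(x) - data||^2 + tau*TV(x)` by fast proximal-gradient
#' iteration. The monotone variant keeps the previous iterate whenever the
#' FISTA candidate would increase the objective, so the objective trace is
#' non-increasing by construction.
#'
#' @param op,adj Linear operator and its adjoint, as functions of arrays; they
#'   must pass the inner-product (dot-product) test.
#' @param data Observed data, shape of `op(x)`.
#' @param cfg A [fista_config()].
#' @param x0 Initial iterate (default zeros, shape of `adj(data)`).
#' @param prox Proximal map `function(x, weight)`; defaults to [tv_prox()] on
#'   the whole array with `cfg$inner_iterations` dual steps (plus a zero clamp
#'   when `cfg$nonnegativity`).
#' @param tv_fun TV evaluator matching `prox` (for the objective trace).
#' @param lipschitz Optional Lipschitz bound L of the data-fidelity gradient
#'   (the squared spectral norm of `op`); a warning is issued if
#'   `step_size > 1/L`.
#' @return List with `solution` and `report` (objective/fidelity/TV traces,
#'   monotone fallback count, converged flag).
#' @export
fista_solve <- function(op, adj, data, cfg = fista_config(), x0 = NULL,
                        prox = NULL, tv_fun = NULL, lipschitz = NULL) {
  stopifnot(inherits(cfg, "fista_config"))
  alpha <- cfg$step_size
  tau <- cfg$tv_weight
  if (!is.null(lipschitz) && alpha > 1 / lipschitz)
    warning(sprintf("step size %.3g exceeds 1/L = %.3g; FISTA may diverge",
                    alpha, 1 / lipschitz))
  if (is.null(prox)) {
    prox <- function(x, w) {
      y <- if (w > 0) tv_prox(x, w, cfg$inner_iterations) else x
      if (cfg$nonnegativity) pmax(y, 0) else y
    }
  }
  if (is.null(tv_fun)) tv_fun <- tv_norm
  if (is.null(x0)) x0 <- adj(data) * 0
  objective <- function(x) {
    r <- op(x) - data
    fid <- 0.5 * sum(r^2)
    tv <- if (tau > 0) tau * tv_fun(x) else 0
    c(fid = fid, tv = tv)
  }
  x_prev <- x0
  y <- x0
  t_k <- 1
  ob <- objective(x0)
  F_prev <- sum(ob)
  trace_fid <- trace_tv <- trace_obj <- numeric(cfg$outer_iterations)
  fallbacks <- 0L
  for (k in seq_len(cfg$outer_iterations)) {
    g <- adj(op(y) - data)
    z <- prox(y - alpha * g, alpha * tau)
    if (any(!is.finite(z)))
      stop(sprintf("NaN/Inf in FISTA iterate at outer iteration %d ", k),
           "(step size too large for this operator?)")
    obz <- objective(z)
    Fz <- sum(obz)
    if (cfg$monotone && Fz > F_prev) {
      x <- x_prev
      Fx <- F_prev
      obx <- c(fid = trace_fid[max(k - 1, 1)], tv = trace_tv[max(k - 1, 1)])
      if (k == 1L) obx <- ob
      fallbacks <- fallbacks + 1L
    } else {
      x <- z
      Fx <- Fz
      obx <- obz
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- x + (t_k / t_next) * (z - x) + ((t_k - 1) / t_next) * (x - x_prev)
    x_prev <- x
    t_k <- t_next
    F_prev <- Fx
    trace_fid[k] <- obx[["fid"]]; trace_tv[k] <- obx[["tv"]]
    trace_obj[k] <- Fx
  }
  list(solution = x_prev,
       report = list(objective = trace_obj, fidelity = trace_fid,
                     tv = trace_tv, fallbacks = fallbacks,
                     converged = !any(!is.finite(trace_obj))))
}

# fast matrix specialization of tv_prox (the traction components are 2D and
# the prox sits in the innermost loop of the solver)
tv_prox_2d <- function(x, weight, inner_iterations) {
  n <- nrow(x); m <- ncol(x)
  p1 <- q1 <- matrix(0, n, m)   # dual variable, row differences
  p2 <- q2 <- matrix(0, n, m)   # dual variable, column differences
  t_k <- 1
  step <- 1 / (8 * weight)
  i1 <- seq_len(n - 1L); j1 <- seq_len(m - 1L)
  for (it in seq_len(inner_iterations)) {
    # divergence (adjoint of forward differences) of the extrapolated dual
    d1 <- -q1; d1[2:n, ] <- d1[2:n, ] + q1[i1, ]
    d1[n, ] <- q1[n - 1L, ]
    d2 <- -q2; d2[, 2:m] <- d2[, 2:m] + q2[, j1]
    d2[, m] <- q2[, m - 1L]
    r <- x - weight * (d1 + d2)
    g1 <- matrix(0, n, m); g1[i1, ] <- r[2:n, ] - r[i1, ]
    g2 <- matrix(0, n, m); g2[, j1] <- r[, 2:m] - r[, j1]
    p1n <- q1 + step * g1
    p2n <- q2 + step * g2
    scl <- 1 / pmax(1, sqrt(p1n^2 + p2n^2))
    p1n <- p1n * scl; p2n <- p2n * scl
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    mom <- (t_k - 1) / t_next
    q1 <- p1n + mom * (p1n - p1); q2 <- p2n + mom * (p2n - p2)
    p1 <- p1n; p2 <- p2n
    t_k <- t_next
  }
  d1 <- -p1; d1[2:n, ] <- d1[2:n, ] + p1[i1, ]; d1[n, ] <- p1[n - 1L, ]
  d2 <- -p2; d2[, 2:m] <- d2[, 2:m] + p2[, j1]; d2[, m] <- p2[, m - 1L]
  x - weight * (d1 + d2)
}

# internal: forward/adjoint on raw [nx, ny, 3] traction arrays
kernel_forward <- function(kernel, Tarr) {
  nx <- kernel$nx; ny <- kernel$ny; nd <- length(kernel$depths)
  FT <- lapply(1:3, function(b) fft(pad2(Tarr[, , b], kernel$Px, kernel$Py)))
  u <- array(0, c(nx, ny, nd, 3))
  for (d in seq_len(nd)) for (a in 1:3) {
    acc <- kernel$Khat[, , d, a, 1] * FT[[1]] +
           kernel$Khat[, , d, a, 2] * FT[[2]] +
           kernel$Khat[, , d, a, 3] * FT[[3]]
    u[, , d, a] <- Re(ifftn(acc))[seq_len(nx), seq_len(ny)]
  }
  u
}

kernel_adjoint <- function(kernel, u) {
  nx <- kernel$nx; ny <- kernel$ny; nd <- length(kernel$depths)
  FU <- vector("list", 3L * nd)
  Tarr <- array(0, c(nx, ny, 3))
  for (b in 1:3) {
    acc <- matrix(complex(real = 0), kernel$Px, kernel$Py)
    for (d in seq_len(nd)) for (a in 1:3) {
      i <- (d - 1) * 3 + a
      if (is.null(FU[[i]])) FU[[i]] <- fft(pad2(u[, , d, a],
                                                kernel$Px, kernel$Py))
      acc <- acc + Conj(kernel$Khat[, , d, a, b]) * FU[[i]]
    }
    Tarr[, , b] <- Re(ifftn(acc))[seq_len(nx), seq_len(ny)]
  }
  Tarr
}

# deterministic power iteration for the spectral norm of op (via op^t op)
operator_norm <- function(op, adj, x_shape, iterations = 20L) {
  x <- with_seed(1L, array(rnorm(prod(x_shape)), x_shape))
  x <- x / sqrt(sum(x^2))
  lam <- 1
  for (i in seq_len(iterations)) {
    y <- adj(op(x))
    lam <- sqrt(sum(y^2))
    if (lam == 0) return(0)
    x <- y / lam
  }
  sqrt(lam)   # ||op||_2
}

#' Reconstruct surface tractions from a displacement field
#'
#' Solves the TV-regularized inverse problem `argmin_T 0.5*||u - G T||^2 +
#' tau*||grad T||_1` with monotone FISTA, where G is the elastic half-space
#' Green's operator sampled at the displacement field's depth planes
#' (by default the two planes nearest the gel surface). The operator is
#' normalized to unit spectral norm and the data to unit maximum so that the
#' default step size and TV weight apply regardless of units; TV acts
#' isotropically on each traction component independently.
#'
#' @param field A complete `displacement_field` (invalid nodes infilled), um.
#'   Fields with more than two depth planes are restricted to the two planes
#'   nearest the surface.
#' @param substrate An [elastic_substrate()].
#' @param cfg A [fista_config()].
#' @param kernel Optional pre-sampled [sample_greens_kernel()]; otherwise
#'   sampled at the field's grid pitch and depth planes.
#' @return A `traction_field` (Pa) at z = 0 on the field's lateral grid, with
#'   attribute `report` (the solver trace).
#' @export
reconstruct_traction <- function(field, substrate, cfg = fista_config(),
                                 kernel = NULL) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(substrate, "elastic_substrate"))
  if (length(field$z) > 2L) {
    keep <- order(field$z)[1:2]
    field <- new_displacement_field(field$x, field$y, field$z[keep],
                                    field$u[, , keep, , drop = FALSE],
                                    field$valid[, , keep, drop = FALSE],
                                    field$quality[, , keep, drop = FALSE])
  }
  nx <- length(field$x); ny <- length(field$y)
  pitch <- c(if (nx > 1) diff(field$x)[1] else 1,
             if (ny > 1) diff(field$y)[1] else 1)
  if (is.null(kernel))
    kernel <- sample_greens_kernel(c(nx, ny), pitch, field$z, substrate)
  else if (kernel$nx != nx || kernel$ny != ny ||
           !isTRUE(all.equal(kernel$depths, field$z)))
    stop("kernel grid/depths do not match the displacement field")
  grid <- list(x = field$x, y = field$y, pitch = pitch)
  s_u <- sqrt(mean(field$u^2))
  if (s_u == 0) {
    out <- new_traction_field(matrix(0, nx, ny), matrix(0, nx, ny),
                              matrix(0, nx, ny), grid)
    attr(out, "report") <- list(objective = 0, fidelity = 0, tv = 0,
                                fallbacks = 0L, converged = TRUE)
    return(out)
  }
  op0 <- function(Tarr) kernel_forward(kernel, Tarr)
  adj0 <- function(u) kernel_adjoint(kernel, u)
  L <- operator_norm(op0, adj0, c(nx, ny, 3))
  # scale so that the configured step size is the critical step 1/L of the
  # normalized operator (step and TV weights are dimensionless)
  cs <- L * sqrt(cfg$step_size)
  op <- function(Tarr) op0(Tarr) / cs
  adj <- function(u) adj0(u) / cs
  u_hat <- field$u / s_u
  prox <- function(x, w) {
    if (w == 0) return(x)
    for (b in 1:3) x[, , b] <- tv_prox(x[, , b], w, cfg$inner_iterations)
    x
  }
  tv3 <- function(x) sum(vapply(1:3, function(b) tv_norm(x[, , b]),
                                numeric(1)))
  sol <- fista_solve(op, adj, u_hat, cfg, prox = prox, tv_fun = tv3,
                     lipschitz = 1 / cfg$step_size)
  Tarr <- sol$solution * (s_u / cs)
  out <- new_traction_field(Tarr[, , 1], Tarr[, , 2], Tarr[, , 3], grid)
  attr(out, "report") <- sol$report
  out
}

#' Per-node local least-squares traction fit (cross-check mode)
#'
#' Fits each traction vector independently from the displacement vectors in a
#' local neighbourhood (default 10 x 10 lateral nodes x all depth planes),
#' assuming the traction is concentrated at the node. Unregularized; intended
#' as an independent sanity check of [reconstruct_traction()], not as the
#' production solver.
#'
#' @param field A complete `displacement_field` (um).
#' @param substrate An [elastic_substrate()].
#' @param patch Lateral half-width of the neighbourhood in nodes.
#' @return A `traction_field` (Pa).
#' @export
local_traction_fit <- function(field, substrate, patch = 5L) {
  nx <- length(field$x); ny <- length(field$y)
  pitch <- c(diff(field$x)[1], diff(field$y)[1])
  area_scale <- pitch[1] * pitch[2] * 1e-12 * 1e6   # Pa on a cell -> um
  tx <- ty <- tz <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    ii <- max(1, i - patch):min(nx, i + patch)
    jj <- max(1, j - patch):min(ny, j + patch)
    rows <- NULL; rhs <- NULL
    for (d in seq_along(field$z)) {
      dx <- field$x[ii] - field$x[i]
      dy <- field$y[jj] - field$y[j]
      X <- matrix(dx, length(ii), length(jj))
      Y <- matrix(dy, length(ii), length(jj), byrow = TRUE)
      z <- field$z[d]
      # avoid the singular point by a quarter-cell offset
      X[X == 0 & Y == 0 & z == 0] <- pitch[1] / 4
      g <- greens_components(X * 1e-6, Y * 1e-6, z * 1e-6, substrate)
      Gm <- rbind(
        cbind(as.vector(g$xx), as.vector(g$xy), as.vector(g$xz)),
        cbind(as.vector(g$yx), as.vector(g$yy), as.vector(g$yz)),
        cbind(as.vector(g$zx), as.vector(g$zy), as.vector(g$zz))) * area_scale
      rows <- rbind(rows, Gm)
      rhs <- c(rhs, as.vector(field$u[ii, jj, d, 1]),
               as.vector(field$u[ii, jj, d, 2]),
               as.vector(field$u[ii, jj, d, 3]))
    }
    sol <- tryCatch(qr.solve(rows, rhs), error = function(e) c(0, 0, 0))
    tx[i, j] <- sol[1]; ty[i, j] <- sol[2]; tz[i, j] <- sol[3]
  }
  new_traction_field(tx, ty, tz,
                     list(x = field$x, y = field$y, pitch = pitch))
}

block_mean_3d <- function(a, f) {
  d <- dim(a)
  dc <- (d %/% f) * f
  a <- a[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), drop = FALSE]
  nd <- dc %/% f
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  array(out, nd)
}

upsample_3d <- function(a, target_dim, f) {
  co <- expand.grid(i = seq_len(target_dim[1]), j = seq_len(target_dim[2]),
                    k = seq_len(target_dim[3]))
  d <- dim(a)
  # fine voxel centre -> coarse block-centre coordinate, clamped to the grid
  cc <- function(x, nc) pmin(pmax((x - (f + 1) / 2) / f + 1, 1), nc)
  array(interp3_trilinear(a, cc(co$i, d[1]), cc(co$j, d[2]), cc(co$k, d[3])),
        target_dim)
}

#' Two-stage multiscale TV deconvolution of a volume
#'
#' Deconvolves a volume against a PSF by monotone TV-FISTA in two stages:
#' the volume is first down-sampled (factor 3), deconvolved with the
#' first-stage parameters, up-sampled to the original size, and deconvolved
#' again with the second-stage parameters. Defaults are the refractive-index
#' reconstruction schedule (alpha = tau = 0.003, 100/75 iterations, then
#' alpha = tau = 0.006, 50/25), with an optional non-negativity constraint on
#' the contrast.
#'
#' @param vol Blurred [ri_volume()] or 3D array.
#' @param psf Point-spread function, centred in its own (odd-sized) array;
#'   normalized internally to unit sum. Must not exceed the volume size.
#' @param stage1,stage2 [fista_config()]s for the two stages.
#' @param downsample Integer down-sampling factor for stage 1 (set to 1 to
#'   skip the multiscale step, e.g. for very small volumes).
#' @param nonnegative Clamp the estimate at zero.
#' @return Deconvolved volume (same class as input) with attribute `report`.
#' @export
deconvolve_volume <- function(vol, psf,
                              stage1 = fista_config(0.003, 0.003, 100L, 75L),
                              stage2 = fista_config(0.006, 0.006, 50L, 25L),
                              downsample = 3L, nonnegative = FALSE) {
  a <- as_volume_array(vol)
  h <- as_volume_array(psf)
  if (any(dim(h) > dim(a))) stop("PSF larger than the volume")
  s <- sum(h)
  if (s <= 0) stop("PSF must have positive sum")
  h <- h / s
  run_stage <- function(data, hh, cfg, x0) {
    d <- dim(data)
    hp <- array(0, d)
    hp[seq_len(dim(hh)[1]), seq_len(dim(hh)[2]), seq_len(dim(hh)[3])] <- hh
    hp <- roll_array(hp, -(dim(hh) - 1L) %/% 2L)
    Hhat <- fft(hp)
    s_u <- max(abs(data))
    if (s_u == 0) return(list(solution = data, report = NULL))
    cs <- max(Mod(Hhat)) * sqrt(cfg$step_size)
    op <- function(x) Re(ifftn(fft(x) * Hhat)) / cs
    adj <- function(x) Re(ifftn(fft(x) * Conj(Hhat))) / cs
    cfg$nonnegativity <- nonnegative
    sol <- fista_solve(op, adj, data / s_u, cfg, x0 = x0 * (cs / s_u),
                       lipschitz = 1 / cfg$step_size)
    sol$solution <- sol$solution * (s_u / cs)
    sol
  }
  reports <- list()
  if (downsample > 1L && all(dim(a) %/% downsample >= dim(h) %/% downsample)
      && all(dim(a) >= 2L * downsample)) {
    a1 <- block_mean_3d(a, downsample)
    h1 <- block_mean_3d(h, downsample)
    if (sum(h1) > 0) h1 <- h1 / sum(h1)
    s1 <- run_stage(a1, h1, stage1, x0 = a1)
    reports$stage1 <- s1$report
    x0 <- upsample_3d(s1$solution, dim(a), downsample)
  } else {
    x0 <- a
  }
  s2 <- run_stage(a, h, stage2, x0 = x0)
  reports$stage2 <- s2$report
  out <- if (inherits(vol, "ri_volume")) ri_volume(s2$solution, vol$pitch)
         else s2$solution
  attr(out, "report") <- reports
  out
}
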
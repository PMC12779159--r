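# Analysis statistics: centre-of-mass transport, the nearest-neighbour
# mixing number, Ripley's K with the CSR crossing radius, and
# cycle-averaged velocity / vorticity fields.

#' Centre-of-mass series of a trajectory record
#'
#' Unweighted mean tracer position per snapshot, the scalar measure of
#' directional clearance.  Times are reported in beat cycles and in two
#' second scales (cycles/18 Hz and cycles/36 Hz) because published figure
#' labels in this literature mix the two conventions.
#'
#' @param traj A `tracer_trajectories` object (or a list of them across
#'   realizations, in which case the mean and standard deviation across
#'   realizations are returned).
#' @return A data frame with `cycle`, `t_18Hz`, `t_36Hz`, `xc`, `yc`, `zc`
#'   (and `*_sd` columns for multi-realization input), positions in
#'   micrometres.
#' @export
center_of_mass <- function(traj) {
  if (inherits(traj, "tracer_trajectories")) {
    com <- apply(traj$positions, c(1, 3), mean)
    return(data.frame(cycle = traj$cycles,
                      t_18Hz = traj$cycles / 18,
                      t_36Hz = traj$cycles / 36,
                      xc = com[, 1], yc = com[, 2], zc = com[, 3]))
  }
  stopifnot(is.list(traj), length(traj) >= 1)
  per <- lapply(traj, center_of_mass)
  cyc <- per[[1]]$cycle
  for (p in per) stopifnot(identical(p$cycle, cyc))
  arr <- simplify2array(lapply(per, function(p) as.matrix(p[, c("xc", "yc", "zc")])))
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  data.frame(cycle = cyc, t_18Hz = cyc / 18, t_36Hz = cyc / 36,
             xc = m[, 1], yc = m[, 2], zc = m[, 3],
             xc_sd = s[, 1], yc_sd = s[, 2], zc_sd = s[, 3])
}

#' Nearest-neighbour mixing number
#'
#' The geometric mean, over tracers of group 1, of the squared distance to
#' the nearest tracer of group 2:
#' \deqn{m = \left( \prod_{i=1}^{N_1} \min_{1 \le j \le N_2}
#'   |z_i - z_j|^2 \right)^{1/N_1}.}
#' Large for fully segregated groups, decaying towards zero as the groups
#' interpenetrate.  The product is accumulated in log space; an exactly
#' coincident pair short-circuits to `m = 0` (attribute `exact_zero`).
#' The statistic is asymmetric in the group order and is computed exactly
#' as written; `symmetrized = TRUE` averages the two orderings.
#'
#' @param group1,group2 N1 x 3 and N2 x 3 position matrices (full
#'   3-vector coordinates).
#' @param symmetrized Average m(1,2) and m(2,1).
#' @return The mixing number (um^2).
#' @examples
#' mixing_number(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1))  # 1
#' @export
mixing_number <- function(group1, group2, symmetrized = FALSE) {
  g1 <- as_points3(group1); g2 <- as_points3(group2)
  stopifnot(nrow(g1) >= 1, nrow(g2) >= 1)
  if (symmetrized)
    return((mixing_number(g1, g2) + mixing_number(g2, g1)) / 2)
  d2min <- nn_sqdist(g1, g2)
  if (any(d2min == 0)) {
    out <- 0
    attr(out, "exact_zero") <- TRUE
    return(out)
  }
  exp(mean(log(d2min)))
}

# squared distance from each row of a to its nearest row of b (chunked)
nn_sqdist <- function(a, b, chunk = 512L) {
  bb <- rowSums(b^2)
  out <- numeric(nrow(a))
  for (start in seq(1, nrow(a), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(a))
    aa <- rowSums(a[idx, , drop = FALSE]^2)
    d2 <- outer(aa, bb, "+") - 2 * a[idx, , drop = FALSE] %*% t(b)
    out[idx] <- pmax(apply(d2, 1, min), 0)
  }
  out
}

#' Mixing-number series between two labelled groups of a trajectory
#'
#' @param traj A `tracer_trajectories` object with labelled tracers.
#' @param groups Character length-2: the two label levels to compare (in
#'   the order entering the asymmetric statistic).  Defaults to the first
#'   two non-empty levels.
#' @return Data frame with `cycle`, `m` and `m_over_m0`.
#' @export
mixing_series <- function(traj, groups = NULL) {
  lv <- levels(traj$labels)
  if (is.null(groups)) {
    nonempty <- lv[table(traj$labels)[lv] > 0]
    if (length(nonempty) < 2)
      stop("need two non-empty tracer groups for a mixing series")
    groups <- nonempty[1:2]
  }
  stopifnot(all(groups %in% lv))
  i1 <- traj$labels == groups[1]
  i2 <- traj$labels == groups[2]
  m <- vapply(seq_along(traj$cycles), function(k)
    as.numeric(mixing_number(traj$positions[k, i1, ],
                             traj$positions[k, i2, ])),
    numeric(1))
  data.frame(cycle = traj$cycles, m = m, m_over_m0 = m / m[1])
}

#' Ripley's K function with CSR crossing radius
#'
#' The unadjusted estimator
#' \deqn{\hat K(r) = \frac{A}{n(n-1)} \sum_{i \ne j} 1(d_{ij} \le r)}
#' on 2-D projected points inside a rectangular window, compared against
#' the complete-spatial-randomness reference \eqn{\pi r^2}.  Values above
#' the reference indicate aggregation (swirl-trapped tracers), below it
#' dispersion.  The crossing radius `r0` is the first radius at which
#' \eqn{\hat K - \pi r^2} crosses from positive to negative after the
#' initial exceedance (linear interpolation); `NA` if the curve never
#' exceeds the reference.  An optional translation edge correction is
#' provided; the default applies none, appropriate when the window is much
#' larger than the crossing scale.
#'
#' @param points n x 2 matrix (or n x 3, in which case x,y are used after
#'   optional `layer` filtering on z).
#' @param window List with `xlim`, `ylim` of the analysis window; points
#'   outside are dropped.
#' @param r_grid Radii at which to evaluate (um).
#' @param correction `"none"` or `"translation"`.
#' @param layer Optional length-2 z-interval; rows of 3-column `points`
#'   with z outside it are dropped.
#' @return An object of class `ripley_k`: data frame `r`, `K`, `csr` plus
#'   attributes `r0`, `n`, `area`.
#' @export
ripley_k <- function(points, window = list(xlim = c(-100, 100),
                                           ylim = c(-100, 100)),
                     r_grid = seq(0.5, 50, by = 0.5),
                     correction = c("none", "translation"),
                     layer = NULL) {
  correction <- match.arg(correction)
  points <- as.matrix(points)
  if (ncol(points) == 3) {
    if (!is.null(layer))
      points <- points[points[, 3] >= layer[1] & points[, 3] <= layer[2], ,
                       drop = FALSE]
    points <- points[, 1:2, drop = FALSE]
  }
  keep <- points[, 1] >= window$xlim[1] & points[, 1] <= window$xlim[2] &
    points[, 2] >= window$ylim[1] & points[, 2] <= window$ylim[2]
  points <- points[keep, , drop = FALSE]
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points inside the window")
  A <- diff(window$xlim) * diff(window$ylim)
  d <- stats::dist(points)
  if (correction == "none") {
    cnt <- vapply(r_grid, function(r) 2 * sum(d <= r), numeric(1))
    K <- A * cnt / (n * (n - 1))
  } else {
    dx <- abs(outer(points[, 1], points[, 1], "-"))
    dy <- abs(outer(points[, 2], points[, 2], "-"))
    wgt <- (diff(window$xlim) - dx) * (diff(window$ylim) - dy)
    dm <- as.matrix(d)
    off <- row(dm) != col(dm)
    K <- vapply(r_grid, function(r)
      sum((dm[off] <= r) / wgt[off]), numeric(1)) * A^2 / (n * (n - 1))
  }
  diffK <- K - pi * r_grid^2
  r0 <- csr_crossing(r_grid, diffK)
  structure(data.frame(r = r_grid, K = K, csr = pi * r_grid^2),
            class = c("ripley_k", "data.frame"),
            r0 = r0, n = n, area = A, correction = correction)
}

# first down-crossing of diffK after the initial exceedance
csr_crossing <- function(r, diffK) {
  above <- which(diffK > 0)
  if (!length(above)) return(NA_real_)
  start <- above[1]
  for (i in seq(start, length(r) - 1)) {
    if (diffK[i] > 0 && diffK[i + 1] <= 0) {
      f <- diffK[i] / (diffK[i] - diffK[i + 1])
      return(r[i] + f * (r[i + 1] - r[i]))
    }
  }
  NA_real_
}

#' @export
print.ripley_k <- function(x, ...) {
  r0 <- attr(x, "r0")
  cat(sprintf("Ripley's K on %d points (window area %g um^2, %s correction)\n",
              attr(x, "n"), attr(x, "area"), attr(x, "correction")))
  if (is.na(r0)) cat("  no CSR crossing (no initial exceedance)\n")
  else cat(sprintf("  CSR crossing radius r0 = %.2f um\n", r0))
  invisible(x)
}

#' Plot Ripley's K against the CSR reference
#'
#' @param x A `ripley_k` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ripley_k <- function(x, ...) {
  graphics::plot(x$r, x$K, type = "l", xlab = "r (um)", ylab = "K(r)", ...)
  graphics::lines(x$r, x$csr, lty = 2, col = "grey40")
  r0 <- attr(x, "r0")
  if (!is.na(r0)) graphics::abline(v = r0, col = "red3", lty = 3)
  invisible(x)
}

#' Cycle-averaged planar velocity field and vorticity
#'
#' Arithmetic mean of the flow over equispaced beat phases of one cycle on
#' a regular grid in the plane `z = z_plane`, with the planar vorticity
#' \eqn{\omega_z = \partial v/\partial x - \partial u/\partial y} by
#' central differences (one-sided at the edges).
#'
#' @param system A [cilia_system()].
#' @param z_plane Height of the analysis plane (um, > 0).
#' @param xlim,ylim Extent of the grid (um).
#' @param spacing Grid spacing (um).
#' @param phases_per_cycle Number of equispaced phases averaged.
#' @return An object of class `field_grid`: list with `x`, `y`
#'   (axes), matrices `u`, `v` (cycle-averaged in-plane velocity) and
#'   `omega_z`.
#' @export
cycle_averaged_field <- function(system, z_plane = 7,
                                 xlim = c(-30, 30), ylim = c(-30, 30),
                                 spacing = 2, phases_per_cycle = 64L) {
  stopifnot(z_plane > 0, phases_per_cycle >= 1)
  xs <- seq(xlim[1], xlim[2], by = spacing)
  ys <- seq(ylim[1], ylim[2], by = spacing)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  pts <- cbind(grid, z_plane)
  period <- 2 * pi / system$law$omega
  acc <- matrix(0, nrow(pts), 3)
  for (k in seq_len(phases_per_cycle)) {
    tt <- (k - 1) * period / phases_per_cycle
    src <- system_sources(system, tt)
    acc <- acc + flow_velocity(pts, src, system$params)
  }
  acc <- acc / phases_per_cycle
  u <- matrix(acc[, 1], length(xs), length(ys))
  v <- matrix(acc[, 2], length(xs), length(ys))
  structure(list(x = xs, y = ys, z_plane = z_plane, u = u, v = v,
                 omega_z = planar_vorticity(u, v, spacing)),
            class = "field_grid")
}

#' Planar vorticity of a gridded velocity field
#'
#' \eqn{\omega_z = \partial v / \partial x - \partial u / \partial y} by
#' central differences in the grid interior and one-sided differences at
#' the edges.  `u[i, j]` is the x-velocity at `x[i]`, `y[j]`.
#'
#' @param u,v Velocity component matrices (x by y).
#' @param spacing Grid spacing (um).
#' @return Matrix of the same shape.
#' @export
planar_vorticity <- function(u, v, spacing) {
  dvdx <- grad_axis1(v, spacing)
  dudy <- t(grad_axis1(t(u), spacing))
  dvdx - dudy
}

# d/dx along the first index, central inside, one-sided at edges
grad_axis1 <- function(m, h) {
  n <- nrow(m)
  out <- m * 0
  if (n >= 3) out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
  out[1, ] <- (m[2, ] - m[1, ]) / h
  out[n, ] <- (m[n, ] - m[n - 1, ]) / h
  out
}

#' Export a cycle-averaged field as tidy CSV
#'
#' One row per grid node: `x`, `y`, `z`, `u`, `v`, `omega_z`.
#'
#' @param field A `field_grid` from [cycle_averaged_field()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_field_csv <- function(field, file) {
  g <- expand.grid(ix = seq_along(field$x), iy = seq_along(field$y))
  df <- data.frame(x = field$x[g$ix], y = field$y[g$iy],
                   z = field$z_plane,
                   u = field$u[cbind(g$ix, g$iy)],
                   v = field$v[cbind(g$ix, g$iy)],
                   omega_z = field$omega_z[cbind(g$ix, g$iy)])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf(
    "Cycle-averaged field at z = %g um: %d x %d grid, max speed %.3g um/s\n",
    x$z_plane, length(x$x), length(x$y), max(sqrt(x$u^2 + x$v^2))))
  cat(sprintf("  vorticity range [%.3g, %.3g] 1/s\n",
              min(x$omega_z), max(x$omega_z)))
  invisible(x)
}

#' Plot a cycle-averaged field as arrows over the vorticity map
#'
#' @param x A `field_grid` object.
#' @param arrow_scale Multiplier converting velocity to arrow length.
#' @param ... Passed to [graphics::image()].
#' @export
plot.field_grid <- function(x, arrow_scale = NULL, ...) {
  graphics::image(x$x, x$y, x$omega_z,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "x (um)", ylab = "y (um)", ...)
  spd <- sqrt(x$u^2 + x$v^2)
  if (is.null(arrow_scale))
    arrow_scale <- 0.8 * (x$x[2] - x$x[1]) / max(spd, 1e-12)
  g <- expand.grid(ix = seq_along(x$x), iy = seq_along(x$y))
  keep <- spd[cbind(g$ix, g$iy)] > 0.02 * max(spd)
  g <- g[keep, ]
  graphics::arrows(x$x[g$ix], x$y[g$iy],
                   x$x[g$ix] + arrow_scale * x$u[cbind(g$ix, g$iy)],
                   x$y[g$iy] + arrow_scale * x$v[cbind(g$ix, g$iy)],
                   length = 0.03, col = "grey20")
  invisible(x)
}
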
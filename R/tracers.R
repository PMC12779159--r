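# Passive massless tracers: lattice seeding with group labels, and RK4
# advection through the time-dependent cilia-driven flow.

#' Seed tracers on a regular lattice with group labels
#'
#' @param region Named list or vector pairs giving the box: `xlim`, `ylim`,
#'   `zlim` (micrometres, `zlim >= 0`).
#' @param n Approximate tracer count; the realized count is the product of
#'   per-axis lattice sizes chosen proportional to the box edges.
#' @param labeling Group labelling rule: `"none"`, `"x4"` (quartiles of
#'   initial x, the four-colour convention), `"zhalf"` (bottom/top half by
#'   initial z), or `"zband"` (bands given by `breaks`).
#' @param breaks Numeric break points for `"zband"` labelling.
#' @return An object of class `tracer_set`: list with `positions` (P x 3),
#'   `initial_positions` and immutable `labels` (factor).
#' @examples
#' tr <- seed_tracers(list(xlim = c(-20, 20), ylim = c(-20, 20),
#'                         zlim = c(5, 9)), n = 200, labeling = "zhalf")
#' table(tr$labels)
#' @export
seed_tracers <- function(region, n = 500,
                         labeling = c("none", "x4", "zhalf", "zband"),
                         breaks = NULL) {
  labeling <- match.arg(labeling)
  xl <- region$xlim; yl <- region$ylim; zl <- region$zlim
  stopifnot(length(xl) == 2, length(yl) == 2, length(zl) == 2,
            xl[1] < xl[2], yl[1] < yl[2], zl[1] <= zl[2], zl[1] >= 0, n >= 1)
  ext <- c(diff(xl), diff(yl), max(diff(zl), 1e-9))
  s <- (n / prod(ext))^(1 / 3)             # ideal linear tracer density
  nz <- if (diff(zl) == 0) 1L else max(2L, round(ext[3] * s))
  m <- n / nz
  nx <- max(2L, round(sqrt(m * ext[1] / ext[2])))
  ny <- max(2L, round(m / nx))
  grid <- expand.grid(x = seq(xl[1], xl[2], length.out = nx),
                      y = seq(yl[1], yl[2], length.out = ny),
                      z = if (nz == 1) zl[1]
                          else seq(zl[1], zl[2], length.out = nz))
  pos <- as.matrix(grid)
  dimnames(pos) <- NULL
  labels <- switch(
    labeling,
    none = factor(rep("all", nrow(pos))),
    x4 = cut(pos[, 1], breaks = seq(xl[1], xl[2], length.out = 5),
             include.lowest = TRUE,
             labels = c("black", "blue", "green", "red")),
    zhalf = factor(ifelse(pos[, 3] < mean(zl), "bottom", "top"),
                   levels = c("bottom", "top")),
    zband = {
      if (is.null(breaks)) stop("labeling = 'zband' needs breaks")
      cut(pos[, 3], breaks = breaks, include.lowest = TRUE)
    })
  structure(list(positions = pos, initial_positions = pos, labels = labels),
            class = "tracer_set")
}

#' @export
print.tracer_set <- function(x, ...) {
  cat(sprintf("Tracer set: %d tracers, groups: %s\n", nrow(x$positions),
              paste(levels(x$labels), collapse = ", ")))
  invisible(x)
}

#' Integrator settings for tracer advection
#'
#' @param scheme `"rk4"` (default) or `"euler"`.
#' @param steps_per_cycle Integration steps per beat cycle (>= 20 for the
#'   rk4 accuracy contract).
#' @param duration_cycles Number of beat cycles to integrate.
#' @param sample_every Snapshot cadence in cycles.
#' @return An object of class `integrator_spec`.
#' @export
integrator_spec <- function(scheme = c("rk4", "euler"),
                            steps_per_cycle = 100L,
                            duration_cycles = 100L,
                            sample_every = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(steps_per_cycle >= 1, duration_cycles >= 1, sample_every >= 1)
  if (scheme == "rk4" && steps_per_cycle < 20)
    warning("fewer than 20 rk4 steps per cycle voids the accuracy contract")
  structure(list(scheme = scheme,
                 steps_per_cycle = as.integer(steps_per_cycle),
                 duration_cycles = as.integer(duration_cycles),
                 sample_every = as.integer(sample_every)),
            class = "integrator_spec")
}

#' Advect tracers through the cilia-driven flow
#'
#' Integrates \eqn{dx/dt = u(x, t)} with the chosen scheme, evaluating the
#' flow at the instantaneous rod phases (sub-stage times included).  The
#' boundaries are open: tracers may leave the patch laterally and are never
#' re-injected.  The wall-corrected flow vanishes at z = 0, so tracers
#' cannot cross the wall; steps that land below `-1e-6` um (a numerics
#' failure) raise a warning and are clamped to z = 0.
#'
#' @param tracers A [tracer_set()].
#' @param system A [cilia_system()], or a function `f(x, t)` mapping a
#'   K x 3 position matrix and a time to a K x 3 velocity matrix (useful
#'   for integrator verification on analytic fields; the "cycle" is then
#'   one unit of `t`).
#' @param integrator An [integrator_spec()].
#' @param verbose Print a progress line every 10% of the run.
#' @return An object of class `tracer_trajectories`: list with `cycles`
#'   (snapshot times in beat cycles), `times` (seconds), `positions`
#'   (snapshots x tracers x 3 array), `labels`, and the specs used.
#' @export
advect <- function(tracers, system, integrator = integrator_spec(),
                   verbose = FALSE) {
  period <- if (is.function(system)) 1 else 2 * pi / system$law$omega
  dt <- period / integrator$steps_per_cycle
  nstep <- integrator$steps_per_cycle * integrator$duration_cycles
  keep_every <- integrator$sample_every * integrator$steps_per_cycle
  x <- tracers$positions
  snaps <- list(x)
  snap_cycles <- 0
  clamped <- FALSE

  if (is.function(system)) {
    field <- function(xx, tt, tabs, key) system(xx, tabs)
  } else {
    # The rod geometry (and hence the assembled force set, including the
    # mobility solve) is periodic in the beat, and every integrator stage
    # falls on one of 3 * steps_per_cycle phases.  Sources are therefore
    # computed once per distinct stage phase and reused for all cycles,
    # which makes the mobility forcing mode affordable.
    src_cache <- vector("list", 3L * integrator$steps_per_cycle)
    field <- function(xx, tt, tabs, key) {
      src <- src_cache[[key]]
      if (is.null(src)) {
        src <- system_sources(system, tt)
        src_cache[[key]] <<- src
      }
      flow_velocity(xx, src, system$params)
    }
  }

  # The length law has one-sided derivatives at the stroke switches
  # (phases 0 and pi).  With an even steps_per_cycle the switches fall
  # exactly on step boundaries; nudging the first and last stage times
  # into the step interior makes every stage sample the branch active
  # inside the step, preserving the integrator's order.
  nudge <- 1e-9 * dt
  spc <- integrator$steps_per_cycle
  for (nstep_i in seq_len(nstep)) {
    km <- (nstep_i - 1L) %% spc          # step index within the cycle
    t0 <- km * dt                        # stage times taken modulo a cycle
    ta <- (nstep_i - 1L) * dt            # absolute time (function fields)
    if (integrator$scheme == "rk4") {
      k1 <- field(x, t0 + nudge, ta + nudge, 3L * km + 1L)
      k2 <- field(x + dt / 2 * k1, t0 + dt / 2, ta + dt / 2, 3L * km + 2L)
      k3 <- field(x + dt / 2 * k2, t0 + dt / 2, ta + dt / 2, 3L * km + 2L)
      k4 <- field(x + dt * k3, t0 + dt - nudge, ta + dt - nudge,
                  3L * km + 3L)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    } else {
      x <- x + dt * field(x, t0 + nudge, ta + nudge, 3L * km + 1L)
    }
    if (!is.function(system)) {
      below <- x[, 3] < -1e-6
      if (any(below)) {
        clamped <- TRUE
        x[below, 3] <- 0
      }
      x[, 3] <- pmax(x[, 3], 0)
    }
    if (nstep_i %% keep_every == 0) {
      snaps[[length(snaps) + 1]] <- x
      snap_cycles <- c(snap_cycles, nstep_i / integrator$steps_per_cycle)
    }
    if (verbose && nstep_i %% max(1, nstep %/% 10) == 0)
      message(sprintf("  cycle %.1f / %d",
                      nstep_i / integrator$steps_per_cycle,
                      integrator$duration_cycles))
  }
  if (clamped)
    warning("tracer stepped below z = -1e-6 um and was clamped to the wall")
  positions <- array(unlist(snaps),
                     dim = c(nrow(x), 3, length(snaps)))
  positions <- aperm(positions, c(3, 1, 2))
  structure(list(cycles = snap_cycles,
                 times = snap_cycles * period,
                 positions = positions,
                 labels = tracers$labels,
                 initial_positions = tracers$initial_positions,
                 integrator = integrator),
            class = "tracer_trajectories")
}

#' @export
print.tracer_trajectories <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf(
    "Tracer trajectories: %d tracers, %d snapshots over %g beat cycles\n",
    d[2], d[1], max(x$cycles)))
  fin <- final_displacement(x)
  cat(sprintf("  mean displacement (um): dx=%.3f dy=%.3f dz=%.3f\n",
              fin[1], fin[2], fin[3]))
  invisible(x)
}

#' Mean final tracer displacement
#'
#' @param traj A `tracer_trajectories` object.
#' @return Length-3 named vector, micrometres.
#' @export
final_displacement <- function(traj) {
  d <- dim(traj$positions)
  last <- traj$positions[d[1], , ]
  first <- traj$positions[1, , ]
  out <- colMeans(last - first)
  names(out) <- c("dx", "dy", "dz")
  out
}

#' Plot tracer trajectories (top view)
#'
#' Scatter of final tracer positions coloured by group, with initial
#' positions in grey.
#'
#' @param x A `tracer_trajectories` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tracer_trajectories <- function(x, ...) {
  d <- dim(x$positions)
  fin <- x$positions[d[1], , ]
  ini <- x$positions[1, , ]
  cols <- as.integer(x$labels)
  graphics::plot(ini[, 1], ini[, 2], col = "grey80", pch = 16, cex = 0.4,
                 xlab = "x (um)", ylab = "y (um)",
                 main = sprintf("tracers after %g cycles", max(x$cycles)),
                 ...)
  graphics::points(fin[, 1], fin[, 2], col = cols + 1, pch = 16, cex = 0.5)
  invisible(x)
}
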
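# A cilia system: rods + beat law + flow parameters, with the per-time
# Stokeslet assembly used by the advection loop and the field analyses.

#' Assemble a cilia-driven flow system
#'
#' Binds a rod layout, a beat law and flow parameters into the object all
#' simulations operate on.  If `params$gamma` is unset and the forcing is
#' resistive, the drag coefficient is calibrated once (see
#' [calibrate_gamma()]) and stored.
#'
#' @param rods List of [rod_config()] (e.g. from [build_cluster()],
#'   [build_array()], [build_patch()], possibly through [assign_phases()]).
#' @param law A [beat_law()].
#' @param params A [flow_params()].
#' @return An object of class `cilia_system`.
#' @examples
#' sys <- cilia_system(build_cluster())
#' flow_velocity(c(0, 0, 8), system_sources(sys, 0), sys$params)
#' @export
cilia_system <- function(rods, law = beat_law(), params = flow_params()) {
  stopifnot(length(rods) >= 1)
  if (params$forcing_mode == "resistive" && is.null(params$gamma))
    params$gamma <- calibrate_gamma(law, params)
  structure(list(rods = rods, law = law, params = params,
                 cluster_id = attr(rods, "cluster_id")),
            class = "cilia_system")
}

#' @export
print.cilia_system <- function(x, ...) {
  nr <- length(x$rods)
  ncl <- if (is.null(x$cluster_id)) 1L else length(unique(x$cluster_id))
  offs <- vapply(x$rods, function(r) r$phase_offset, numeric(1))
  cat(sprintf("Cilia system: %d rods in %d cluster(s), %d nodes per rod\n",
              nr, ncl, length(x$law$node_fractions)))
  cat(sprintf("  beat: %.3g Hz, theta in [%.2g, %.2g] (%s)\n",
              x$law$omega / (2 * pi), x$law$theta_min, x$law$theta_max,
              x$law$theta_shape))
  if (all(offs == 0)) cat("  synchronous beating (all phase offsets 0)\n")
  else cat(sprintf("  metachronal: phase offsets in [%.3g, %.3g] rad\n",
                   min(offs), max(offs)))
  cat(sprintf("  forcing: %s%s, epsilon = %.3g, wall = %s\n",
              x$params$forcing_mode,
              if (x$params$forcing_mode == "resistive")
                sprintf(" (gamma = %.4g)", x$params$gamma) else "",
              x$params$epsilon, x$params$wall))
  invisible(x)
}

#' Instantaneous Stokeslet sources of a system
#'
#' Computes all node positions and the forces implied by the prescribed
#' node velocities at time `t`.  Rods sharing a phase offset share node
#' geometry (poses are translates), so offsets are computed once per
#' distinct phase.
#'
#' @param system A [cilia_system()].
#' @param t Time in seconds.
#' @return A [stokeslet_set()]; attribute `velocities` carries the
#'   prescribed node velocities (um/s).
#' @export
system_sources <- function(system, t) {
  law <- system$law
  offs <- vapply(system$rods, function(r) r$phase_offset, numeric(1))
  uoff <- unique(offs)
  nn <- length(law$node_fractions)
  nr <- length(system$rods)
  bases <- t(vapply(system$rods, function(r) r$base, numeric(3)))
  # poses of rods sharing a phase offset are translates of one another
  cache <- lapply(uoff, function(o)
    node_offsets(phase_at(t, o, law$omega), law))
  grp <- match(offs, uoff)
  pos <- do.call(rbind, lapply(grp, function(g) cache[[g]]$positions)) +
    bases[rep(seq_len(nr), each = nn), ]
  vel <- do.call(rbind, lapply(grp, function(g) cache[[g]]$velocities)) *
    law$omega
  if (system$params$forcing_mode == "resistive") {
    src <- stokeslet_set(pos, system$params$gamma * vel,
                         system$params$epsilon)
  } else {
    src <- assemble_forces(pos, vel, system$params)
  }
  attr(src, "velocities") <- vel
  src
}
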
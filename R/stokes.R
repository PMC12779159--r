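# Zero-Reynolds-number flow driven by regularized point forces over a
# no-slip wall.  The heavy pairwise kernels live in src/kernels.cpp.

#' Regularized force-spreading blob
#'
#' \eqn{\psi_\epsilon(r) = 15\epsilon^4 / (8\pi (r^2+\epsilon^2)^{7/2})}:
#' positive, monotone decreasing, unit mass over 3-space.  The width
#' \eqn{\epsilon} plays the role of the cilium thickness.
#'
#' @param r Distance in micrometres (vectorised), `r >= 0`.
#' @param epsilon Blob width in micrometres.
#' @return Density in 1/um^3.
#' @export
psi_blob <- function(r, epsilon = 0.1) {
  stopifnot(epsilon > 0, all(r >= 0))
  15 * epsilon^4 / (8 * pi * (r^2 + epsilon^2)^(7 / 2))
}

#' A set of regularized Stokeslets
#'
#' @param positions M x 3 matrix of source positions (micrometres).  With a
#'   wall all sources must sit strictly above it (z > 0).
#' @param forces M x 3 matrix of force vectors.
#' @param epsilon Blob width (micrometres).
#' @return An object of class `stokeslet_set`.
#' @export
stokeslet_set <- function(positions, forces, epsilon = 0.1) {
  positions <- as_points3(positions)
  forces <- as_points3(forces)
  stopifnot(nrow(positions) == nrow(forces), epsilon > 0,
            all(is.finite(forces)))
  structure(list(positions = positions, forces = forces, epsilon = epsilon),
            class = "stokeslet_set")
}

#' @export
print.stokeslet_set <- function(x, ...) {
  cat(sprintf("Stokeslet set: %d sources, epsilon = %.3g um\n",
              nrow(x$positions), x$epsilon))
  invisible(x)
}

#' Flow parameters
#'
#' The simulation is nondimensionalized: lengths in micrometres, viscosity
#' `mu = 1`.  Stokes flow is linear, so trajectories and flow geometry
#' depend only on the velocity boundary data, not on `mu` and the force
#' scale separately.
#'
#' @param mu Dynamic viscosity (nondimensional).
#' @param forcing_mode `"resistive"` (force on each node proportional to its
#'   prescribed velocity, `f = gamma v`) or `"mobility"` (solve the linear
#'   system so the fluid velocity matches the node velocities exactly).
#' @param gamma Drag coefficient per node, used in resistive mode.  The
#'   default `NULL` means: calibrate once per system with
#'   [calibrate_gamma()] so the fluid speed at an isolated rod tip matches
#'   the prescribed tip speed.
#' @param epsilon Blob width (micrometres).
#' @param wall Enforce the no-slip wall at z = 0 via the image system.
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(mu = 1, forcing_mode = c("resistive", "mobility"),
                        gamma = NULL, epsilon = 0.1, wall = TRUE) {
  forcing_mode <- match.arg(forcing_mode)
  stopifnot(mu > 0, epsilon > 0, is.null(gamma) || gamma > 0)
  structure(list(mu = mu, forcing_mode = forcing_mode, gamma = gamma,
                 epsilon = epsilon, wall = isTRUE(wall)),
            class = "flow_params")
}

#' Velocity field of a set of regularized Stokeslets
#'
#' Superposes the regularized free-space kernel and, when `wall = TRUE`,
#' the exact image system that cancels the velocity on the plane z = 0.
#'
#' @param points K x 3 matrix (or length-3 vector) of evaluation points.
#'   With a wall, points must satisfy z >= 0.
#' @param src A [stokeslet_set()].
#' @param params A [flow_params()] (only `mu` and `wall` are used; the blob
#'   width is carried by `src`).
#' @return K x 3 matrix of velocities.
#' @export
flow_velocity <- function(points, src, params = flow_params()) {
  points <- as_points3(points)
  if (params$wall) {
    if (any(points[, 3] < 0))
      stop("evaluation points below the wall (z < 0)")
    if (any(src$positions[, 3] <= 0))
      stop("all sources must lie strictly above the wall")
  }
  .rs_velocity_cpp(points, src$positions, src$forces,
                   src$epsilon, params$mu, params$wall)
}

#' Free-space regularized Stokeslet velocity
#'
#' @inheritParams flow_velocity
#' @param mu Dynamic viscosity.
#' @return K x 3 matrix of velocities.
#' @export
freespace_velocity <- function(points, src, mu = 1) {
  points <- as_points3(points)
  .rs_velocity_cpp(points, src$positions, src$forces, src$epsilon, mu, FALSE)
}

#' Wall-bounded regularized Stokeslet velocity
#'
#' @inheritParams freespace_velocity
#' @return K x 3 matrix of velocities; exactly zero on z = 0.
#' @export
wall_velocity <- function(points, src, mu = 1) {
  flow_velocity(points, src, flow_params(mu = mu, wall = TRUE))
}

#' Pairwise coupling (mobility) matrix
#'
#' Matrix `G` with 3 x 3 blocks such that the stacked velocities at
#' `points` equal `G %*% as.vector(t(forces))` for unit-epsilon-blob forces
#' at `sources`.  Used for the mobility forcing mode and for reciprocity
#' checks.
#'
#' @param points K x 3 evaluation points.
#' @param sources M x 3 source positions.
#' @param epsilon Blob width.
#' @param mu Viscosity.
#' @param wall Include the wall image system.
#' @return A `3K x 3M` matrix.
#' @export
coupling_matrix <- function(points, sources, epsilon = 0.1, mu = 1,
                            wall = TRUE) {
  .rs_matrix_cpp(as_points3(points), as_points3(sources), epsilon, mu, wall)
}

#' Forces on rod nodes from their prescribed velocities
#'
#' In resistive mode every node carries `f = gamma * v`; in mobility mode
#' the forces solve the dense linear system so that the induced fluid
#' velocity at every node equals its prescribed velocity.
#'
#' @param positions,velocities M x 3 matrices of node positions (z > 0) and
#'   prescribed node velocities.
#' @param params A [flow_params()]; in resistive mode `params$gamma` must
#'   be set (see [calibrate_gamma()]).
#' @return A [stokeslet_set()] carrying the solved forces.
#' @export
assemble_forces <- function(positions, velocities, params = flow_params()) {
  positions <- as_points3(positions)
  velocities <- as_points3(velocities)
  stopifnot(nrow(positions) == nrow(velocities))
  if (params$wall && any(positions[, 3] <= 0))
    stop("node positions must lie strictly above the wall")
  if (params$forcing_mode == "resistive") {
    gamma <- params$gamma
    if (is.null(gamma))
      stop("resistive mode needs params$gamma; see calibrate_gamma()")
    forces <- gamma * velocities
  } else {
    G <- coupling_matrix(positions, positions, params$epsilon, params$mu,
                         params$wall)
    forces <- tryCatch(
      matrix(solve(G, as.vector(t(velocities))), ncol = 3, byrow = TRUE),
      error = function(e)
        stop(sprintf("mobility solve failed (rcond = %.3g): %s",
                     rcond(G), conditionMessage(e)), call. = FALSE))
  }
  stokeslet_set(positions, forces, params$epsilon)
}

#' Calibrate the resistive drag coefficient
#'
#' Chooses `gamma` so that, for an isolated rod at mid effective stroke
#' (\eqn{\phi = \pi/2}), the fluid speed evaluated at the tip node equals
#' the prescribed tip speed.  By linearity this is a single scalar ratio.
#' It fixes the overall velocity scale of the resistive forcing; flow
#' geometry is unaffected.
#'
#' @param law A [beat_law()].
#' @param params A [flow_params()].
#' @return The scalar `gamma`.
#' @export
calibrate_gamma <- function(law = beat_law(), params = flow_params()) {
  off <- node_offsets(pi / 2, law)
  pos <- off$positions
  vel <- off$velocities * law$omega
  src <- stokeslet_set(pos, vel, params$epsilon)  # gamma = 1
  n <- nrow(pos)
  u_tip <- flow_velocity(pos[n, , drop = FALSE], src, params)
  sqrt(sum(vel[n, ]^2)) / sqrt(sum(u_tip^2))
}

# coerce to a K x 3 numeric matrix
as_points3 <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3)
    x <- matrix(as.numeric(x), 1, 3)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 3)
  x
}
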
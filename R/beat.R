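# Prescribed cilium beat kinematics: a rigid rod anchored on the wall,
# rotating counter-clockwise about z at constant angular velocity, long
# during the effective stroke and shortened during recovery.

#' Beat law for a model cilium
#'
#' Defines the prescribed kinematics of a cilium modelled as a rigid
#' rotating rod: azimuthal phase \eqn{\phi(t) = \phi_0 + \omega t}, a
#' phase-dependent rod length \eqn{L(\phi)} (constant during the effective
#' stroke on \eqn{[0, \pi]}, a cubic contraction during recovery on
#' \eqn{(\pi, 2\pi)}), and a polar angle \eqn{\theta(\phi)} confined to
#' `[theta_min, theta_max]`.  With counter-clockwise rotation the effective
#' stroke sweeps the fluid towards negative \eqn{x}, the direction of
#' mucociliary clearance.
#'
#' @param omega Angular velocity in rad/s.  The default \eqn{36\pi}
#'   corresponds to a beat frequency of 18 Hz.
#' @param theta_min,theta_max Bounds of the polar angle (radians, measured
#'   from the wall plane).  Both must lie in \eqn{(0, \pi)} so the rod never
#'   dips below the wall.
#' @param L_fwd Rod length during the effective (forward) stroke, micrometres.
#' @param recovery_coeffs Cubic coefficients `c(c3, c2, c1, c0)` of the
#'   recovery-stroke length law \eqn{L(\phi) = c_3\phi^3 + c_2\phi^2 +
#'   c_1\phi + c_0} evaluated on \eqn{(\pi, 2\pi)}, micrometres.
#' @param theta_shape Interpolation rule for \eqn{\theta(\phi)}.  The
#'   default `"cosine2"` is the pi-periodic law \eqn{\theta = \theta_{min}
#'   + \Delta\theta\,(1 - \cos 2\phi)/2}: the rod passes through the full
#'   polar range once per half-revolution, so the shortened recovery rod
#'   sweeps close to the wall while the extended effective rod does its
#'   work higher up -- the stroke asymmetry that produces net clearance
#'   towards negative x.  `"cosine"` is the 2-pi-periodic alternative
#'   \eqn{\theta_{min} + \Delta\theta (1-\cos\phi)/2} (height-symmetric
#'   between strokes, hence almost no directional pumping), and
#'   `"triangle"` a piecewise-linear variant of it.  All stay within
#'   `[theta_min, theta_max]`.
#' @param nodes_per_rod Number of Stokeslet nodes riding the rod at fixed
#'   fractions \eqn{\sigma_i = i/n} of the instantaneous length.
#'
#' @return An object of class `beat_law`.
#' @examples
#' law <- beat_law()
#' rod_length(pi / 2, law)    # 7 during the effective stroke
#' rod_length(3 * pi / 2, law)  # contracted during recovery
#' @export
beat_law <- function(omega = 36 * pi,
                     theta_min = 0.8, theta_max = 2.4,
                     L_fwd = 7,
                     recovery_coeffs = c(-0.3235, 5.2009, -26.6650, 49.4710),
                     theta_shape = c("cosine2", "cosine", "triangle"),
                     nodes_per_rod = 15L) {
  theta_shape <- match.arg(theta_shape)
  stopifnot(omega > 0, L_fwd > 0,
            theta_min < theta_max,
            theta_min > 0, theta_max < pi,
            length(recovery_coeffs) == 4,
            nodes_per_rod >= 1)
  law <- structure(
    list(omega = omega, theta_min = theta_min, theta_max = theta_max,
         L_fwd = L_fwd, recovery_coeffs = recovery_coeffs,
         theta_shape = theta_shape,
         node_fractions = seq_len(nodes_per_rod) / nodes_per_rod),
    class = "beat_law")
  # recovery branch must stay positive and close to L_fwd at the join
  phis <- seq(pi, 2 * pi, length.out = 257)
  Ls <- rod_length(phis[-length(phis)], law)
  if (any(Ls <= 0) || any(Ls > L_fwd + 0.01))
    stop("recovery length law leaves (0, L_fwd + 0.01] on [pi, 2*pi)")
  law
}

#' @export
print.beat_law <- function(x, ...) {
  cat("Cilium beat law\n")
  cat(sprintf("  omega: %.4g rad/s (frequency %.3g Hz, period %.4g s)\n",
              x$omega, x$omega / (2 * pi), 2 * pi / x$omega))
  cat(sprintf("  polar angle: [%.3g, %.3g] rad (%s law)\n",
              x$theta_min, x$theta_max, x$theta_shape))
  cat(sprintf("  length: %.3g um forward; cubic recovery (%.4g at 3*pi/2)\n",
              x$L_fwd, rod_length(3 * pi / 2, x)))
  cat(sprintf("  %d nodes per rod at sigma = i/%d\n",
              length(x$node_fractions), length(x$node_fractions)))
  invisible(x)
}

#' Beat phase at a given time
#'
#' \eqn{\phi(t) = (\phi_0 + \omega t) \bmod 2\pi}.
#'
#' @param t Time in seconds (vectorised).
#' @param phi0 Phase offset in radians.
#' @param omega Angular velocity in rad/s.
#' @return Phase in `[0, 2*pi)`.
#' @export
phase_at <- function(t, phi0 = 0, omega = 36 * pi) {
  stopifnot(omega > 0)
  (phi0 + omega * t) %% (2 * pi)
}

#' Instantaneous rod length
#'
#' `L_fwd` micrometres throughout the effective stroke
#' (\eqn{\phi \in [0, \pi]}) and the recovery cubic on \eqn{(\pi, 2\pi)}.
#' The printed cubic meets the forward branch at \eqn{\phi = \pi} to within
#' 0.002 um; the discontinuity of the derivative at the stroke switches is
#' resolved one-sidedly by [rod_dlength()].
#'
#' @param phi Phase in `[0, 2*pi)` (vectorised).  Values outside are
#'   rejected; wrap with [phase_at()] first.
#' @param law A [beat_law()].
#' @return Length in micrometres.
#' @export
rod_length <- function(phi, law = beat_law()) {
  if (any(phi < 0 | phi >= 2 * pi))
    stop("phi must lie in [0, 2*pi); wrap with phase_at()")
  cc <- law$recovery_coeffs
  ifelse(phi <= pi, law$L_fwd,
         ((cc[1] * phi + cc[2]) * phi + cc[3]) * phi + cc[4])
}

#' Phase derivative of the rod length (one-sided at stroke switches)
#'
#' @inheritParams rod_length
#' @return dL/dphi in micrometres per radian; 0 on the forward branch.
#' @export
rod_dlength <- function(phi, law = beat_law()) {
  if (any(phi < 0 | phi >= 2 * pi))
    stop("phi must lie in [0, 2*pi); wrap with phase_at()")
  cc <- law$recovery_coeffs
  ifelse(phi <= pi, 0,
         (3 * cc[1] * phi + 2 * cc[2]) * phi + cc[3])
}

#' Polar angle of the rod and its phase derivative
#'
#' The experimental literature constrains only the range of the polar
#' angle; the interpolation in between is a modelling choice.  The default
#' cosine law \eqn{\theta(\phi) = \theta_{min} + (\theta_{max} -
#' \theta_{min}) (1 - \cos\phi)/2} is smooth and \eqn{2\pi}-periodic and
#' keeps node velocities bounded; a triangle-wave alternative is provided
#' for sensitivity checks.
#'
#' @inheritParams rod_length
#' @return A list with components `theta` and `dtheta` (radians and
#'   radians per radian of phase), each the length of `phi`.
#' @export
polar_angle <- function(phi, law = beat_law()) {
  if (any(phi < 0 | phi >= 2 * pi))
    stop("phi must lie in [0, 2*pi); wrap with phase_at()")
  span <- law$theta_max - law$theta_min
  if (law$theta_shape == "cosine2") {
    theta <- law$theta_min + span * (1 - cos(2 * phi)) / 2
    dtheta <- span * sin(2 * phi)
  } else if (law$theta_shape == "cosine") {
    theta <- law$theta_min + span * (1 - cos(phi)) / 2
    dtheta <- span * sin(phi) / 2
  } else if (law$theta_shape == "triangle") {
    up <- phi <= pi
    theta <- ifelse(up, law$theta_min + span * phi / pi,
                    law$theta_max - span * (phi - pi) / pi)
    dtheta <- ifelse(up, span / pi, -span / pi)
  } else {
    stop("unknown theta_shape: ", law$theta_shape)
  }
  list(theta = theta, dtheta = dtheta)
}

#' Configuration of a single rod (base position and phase offset)
#'
#' @param base Numeric length-2 or -3: base coordinates in micrometres.  The
#'   base sits on the wall, so any z-component must be 0.
#' @param phase_offset Initial phase \eqn{\phi_0} in radians.
#' @return An object of class `rod_config`.
#' @export
rod_config <- function(base = c(0, 0), phase_offset = 0) {
  base <- as.numeric(base)
  if (length(base) == 2) base <- c(base, 0)
  stopifnot(length(base) == 3)
  if (base[3] != 0) stop("rod base must sit on the wall (z = 0)")
  structure(list(base = base, phase_offset = as.numeric(phase_offset)),
            class = "rod_config")
}

#' Node positions and analytic node velocities of a beating rod
#'
#' Node \eqn{i} rides at fixed fraction \eqn{\sigma_i} of the instantaneous
#' length, at position
#' \eqn{x_0 + \sigma_i L(\phi) (\cos\theta\cos\phi, \cos\theta\sin\phi,
#' \sin\theta)}.  Velocities are exact time derivatives, including the
#' shortening term \eqn{\sigma_i (dL/d\phi)\, \omega} along the rod axis,
#' with one-sided \eqn{dL/d\phi} at the stroke switches.
#'
#' @param t Time in seconds (scalar).
#' @param rod A [rod_config()].
#' @param law A [beat_law()].
#' @return An object of class `rod_pose`: list with `time`, `phase`,
#'   `node_positions` (n x 3, micrometres) and `node_velocities`
#'   (n x 3, micrometres per second).
#' @export
rod_pose <- function(t, rod = rod_config(), law = beat_law()) {
  phi <- phase_at(t, rod$phase_offset, law$omega)
  off <- node_offsets(phi, law)
  structure(
    list(time = t, phase = phi,
         node_positions = sweep(off$positions, 2, rod$base, "+"),
         node_velocities = off$velocities * law$omega),
    class = "rod_pose")
}

# Node positions relative to the base and d(position)/dphi, shared by all
# rods at the same phase (poses of synchronized rods are translates).
node_offsets <- function(phi, law) {
  L <- rod_length(phi, law)
  dL <- rod_dlength(phi, law)
  th <- polar_angle(phi, law)
  ct <- cos(th$theta); st <- sin(th$theta)
  cp <- cos(phi); sp <- sin(phi)
  ur <- c(ct * cp, ct * sp, st)
  dur <- c(-st * th$dtheta * cp - ct * sp,
           -st * th$dtheta * sp + ct * cp,
           ct * th$dtheta)
  sig <- law$node_fractions
  list(positions = outer(sig, L * ur),
       velocities = outer(sig, dL * ur + L * dur))
}

#' @export
print.rod_pose <- function(x, ...) {
  n <- nrow(x$node_positions)
  cat(sprintf("Rod pose at t = %.4g s (phase %.4g rad), %d nodes\n",
              x$time, x$phase, n))
  cat(sprintf("  tip at (%.3f, %.3f, %.3f) um, tip speed %.3g um/s\n",
              x$node_positions[n, 1], x$node_positions[n, 2],
              x$node_positions[n, 3],
              sqrt(sum(x$node_velocities[n, ]^2))))
  invisible(x)
}
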
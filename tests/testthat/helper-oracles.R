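# Independent oracles used across the suite.  These re-derive reference
# values from closed forms or brute force and never call the kernels they
# are checking.

# Singular (point-force) Stokeslet, scaled by 8*pi*mu like the package
# kernels: u = f/r + (f.y) y / r^3, divided by 8 pi mu.
singular_stokeslet <- function(points, x0, f, mu = 1) {
  t(apply(points, 1, function(p) {
    y <- p - x0
    r <- sqrt(sum(y^2))
    (f / r + sum(f * y) * y / r^3) / (8 * pi * mu)
  }))
}

# Classical singular image-system solution for a point force above a
# plane no-slip wall (force f at x0 = (x, y, h), wall at z = 0).
singular_blake <- function(points, x0, f, mu = 1) {
  h <- x0[3]
  xim <- c(x0[1], x0[2], -h)
  t(apply(points, 1, function(p) {
    y <- p - x0
    R <- p - xim
    r <- sqrt(sum(y^2)); Rn <- sqrt(sum(R^2))
    u <- f / r + sum(f * y) * y / r^3
    u <- u - (f / Rn + sum(f * R) * R / Rn^3)
    for (j in 1:3) {
      if (f[j] == 0) next
      sgn <- if (j == 3) -1 else 1
      ej <- numeric(3); ej[j] <- 1
      Rj <- R[j]; R3 <- R[3]
      d <- h * (ej / Rn^3 - 3 * R * Rj / Rn^5)
      d <- d + c(0, 0, 1) * Rj / Rn^3
      dj3 <- if (j == 3) 1 else 0
      d <- d - (ej * R3 + R * dj3) / Rn^3 + 3 * R * R3 * Rj / Rn^5
      u <- u + f[j] * sgn * 2 * h * d
    }
    u / (8 * pi * mu)
  }))
}

# O(n^2) double-loop Ripley K estimator (no edge correction).
ripley_brute <- function(pts2d, area, r_grid) {
  n <- nrow(pts2d)
  K <- numeric(length(r_grid))
  for (k in seq_along(r_grid)) {
    cnt <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dij <- sqrt(sum((pts2d[i, ] - pts2d[j, ])^2))
      if (dij <= r_grid[k]) cnt <- cnt + 1L
    }
    K[k] <- area * cnt / (n * (n - 1))
  }
  K
}

# Brute-force mixing number straight from the definition (product form,
# small groups only).
mixing_brute <- function(g1, g2) {
  prods <- apply(g1, 1, function(a)
    min(apply(g2, 1, function(b) sum((a - b)^2))))
  prod(prods)^(1 / nrow(g1))
}

# A small random Stokeslet configuration above the wall.
random_stokeslets <- function(n, seed = 1, epsilon = 0.1) {
  set.seed(seed)
  stokeslet_set(
    positions = cbind(runif(n, -10, 10), runif(n, -10, 10),
                      runif(n, 0.5, 8)),
    forces = matrix(rnorm(3 * n), n, 3),
    epsilon = epsilon)
}

# Cheap deterministic tracer box around one cluster.
small_cluster_system <- function(...) {
  cilia_system(build_cluster(), beat_law(...), flow_params())
}
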
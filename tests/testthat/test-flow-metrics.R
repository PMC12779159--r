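# Analysis statistics: centre of mass, mixing number, Ripley's K,
# cycle-averaged fields and vorticity.

fake_traj <- function(positions_list, labels = NULL) {
  # build a minimal trajectory record from a list of P x 3 snapshots
  P <- nrow(positions_list[[1]])
  pos <- array(0, c(length(positions_list), P, 3))
  for (k in seq_along(positions_list)) pos[k, , ] <- positions_list[[k]]
  structure(list(cycles = seq_along(positions_list) - 1,
                 times = (seq_along(positions_list) - 1) / 18,
                 positions = pos,
                 labels = labels %||% factor(rep("all", P))),
            class = "tracer_trajectories")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("centre of mass is the unweighted mean and is constant for stationary tracers", {
  pts <- rbind(c(1, 2, 3), c(-1, -2, 3), c(0, 0, 0))
  tj <- fake_traj(list(pts, pts, pts))
  com <- center_of_mass(tj)
  expect_equal(com$xc, rep(0, 3))
  expect_equal(com$yc, rep(0, 3))
  expect_equal(com$zc, rep(2, 3))
  # two tracers at +/- a sit at the origin
  tj2 <- fake_traj(list(rbind(c(3, -2, 1), c(-3, 2, -1))))
  c2 <- center_of_mass(tj2)
  expect_equal(unlist(c2[1, c("xc", "yc", "zc")]), c(xc = 0, yc = 0, zc = 0))
  # both second scales are reported
  expect_equal(com$t_18Hz, com$cycle / 18)
  expect_equal(com$t_36Hz, com$cycle / 36)
})

test_that("multi-realization centre of mass aggregates mean and sd", {
  t1 <- fake_traj(list(matrix(c(0, 0, 0), 1), matrix(c(2, 0, 0), 1)))
  t2 <- fake_traj(list(matrix(c(0, 0, 0), 1), matrix(c(4, 0, 0), 1)))
  agg <- center_of_mass(list(t1, t2))
  expect_equal(agg$xc, c(0, 3))
  expect_equal(agg$xc_sd, c(0, sd(c(2, 4))))
})

test_that("mixing number reproduces hand-evaluated cases", {
  A <- matrix(c(0, 0, 0), 1); B <- matrix(c(1, 0, 0), 1)
  expect_equal(as.numeric(mixing_number(A, B)), 1)
  # coincident sets give exactly zero with the exact-zero flag
  m0 <- mixing_number(A, A)
  expect_equal(as.numeric(m0), 0)
  expect_true(attr(m0, "exact_zero"))
  A2 <- rbind(c(0, 0, 0), c(0, 0, 2)); B2 <- matrix(c(0, 0, 1), 1)
  expect_equal(as.numeric(mixing_number(A2, B2)), 1)  # (1 * 1)^{1/2}
  # brute-force product oracle on small random groups
  set.seed(21)
  for (rep in 1:5) {
    g1 <- matrix(runif(9, -3, 3), 3, 3)
    g2 <- matrix(runif(15, -3, 3), 5, 3)
    expect_equal(as.numeric(mixing_number(g1, g2)), mixing_brute(g1, g2),
                 tolerance = 1e-12)
  }
  # asymmetric in the group order; the symmetrized option averages
  g1 <- rbind(c(0, 0, 0), c(10, 0, 0)); g2 <- rbind(c(1, 0, 0))
  m12 <- as.numeric(mixing_number(g1, g2))
  m21 <- as.numeric(mixing_number(g2, g1))
  expect_false(isTRUE(all.equal(m12, m21)))
  expect_equal(as.numeric(mixing_number(g1, g2, symmetrized = TRUE)),
               (m12 + m21) / 2)
})

test_that("mixing number is scale-covariant (units of squared distance)", {
  set.seed(8)
  g1 <- matrix(runif(30), 10, 3); g2 <- matrix(runif(30), 10, 3)
  m <- as.numeric(mixing_number(g1, g2))
  m4 <- as.numeric(mixing_number(2 * g1, 2 * g2))
  expect_equal(m4, 4 * m, tolerance = 1e-12)
})

test_that("Ripley K matches the CSR reference for uniform points", {
  set.seed(31)
  n <- 2000
  pts <- cbind(runif(n, -100, 100), runif(n, -100, 100))
  rk <- ripley_k(pts, window = list(xlim = c(-100, 100), ylim = c(-100, 100)),
                 r_grid = c(2, 5, 10))
  expect_equal(rk$K[2], pi * 25, tolerance = 0.10)
  expect_equal(rk$K, rk$csr, tolerance = 0.15)
  # K(0) -> 0 and monotone nondecreasing
  rk2 <- ripley_k(pts, r_grid = seq(0.5, 30, by = 0.5))
  expect_true(all(diff(rk2$K) >= 0))
})

test_that("Ripley K equals brute-force pair counting on small point sets", {
  set.seed(17)
  pts <- cbind(runif(200, -50, 50), runif(200, -50, 50))
  win <- list(xlim = c(-50, 50), ylim = c(-50, 50))
  rg <- c(1, 3, 7, 15, 30)
  rk <- ripley_k(pts, window = win, r_grid = rg)
  expect_equal(rk$K, ripley_brute(pts, 100 * 100, rg), tolerance = 1e-12)
})

test_that("a tight clump yields aggregation then a CSR down-crossing", {
  # a Gaussian clump concentrates nearly all pairs below ~4 sigma, so
  # K(r) ~ A for larger r and the down-crossing sits near sqrt(A / pi);
  # simulation oracle: sigma = 3 in a [-25, 25]^2 window -> r0 ~ 28
  set.seed(12)
  clump <- cbind(rnorm(400, sd = 3), rnorm(400, sd = 3))
  rk <- ripley_k(clump, window = list(xlim = c(-25, 25), ylim = c(-25, 25)),
                 r_grid = seq(0.5, 35, by = 0.5))
  expect_gt(rk$K[rk$r == 2], pi * 4)          # far above CSR at small r
  r0 <- attr(rk, "r0")
  expect_false(is.na(r0))
  expect_gt(r0, 25); expect_lt(r0, 31)
  # interpolated crossing: K - pi r^2 changes sign at r0
  below <- rk$K[rk$r > r0 + 1][1:5] - pi * rk$r[rk$r > r0 + 1][1:5]^2
  expect_true(all(below < 0))
})

test_that("layer selection and window filtering restrict the points used", {
  set.seed(5)
  pts3 <- cbind(runif(500, -50, 50), runif(500, -50, 50), runif(500, 0, 14))
  rk <- ripley_k(pts3, window = list(xlim = c(-50, 50), ylim = c(-50, 50)),
                 r_grid = c(5, 10), layer = c(6, 8))
  expect_equal(attr(rk, "n"), sum(pts3[, 3] >= 6 & pts3[, 3] <= 8))
  expect_error(ripley_k(pts3[1:1, , drop = FALSE], r_grid = 1), "at least 2")
})

test_that("translation edge correction is available and close to the raw estimate away from the boundary scale", {
  set.seed(9)
  pts <- cbind(runif(400, -50, 50), runif(400, -50, 50))
  win <- list(xlim = c(-50, 50), ylim = c(-50, 50))
  raw <- ripley_k(pts, win, r_grid = c(3, 6))
  tc <- ripley_k(pts, win, r_grid = c(3, 6), correction = "translation")
  expect_equal(tc$K, raw$K, tolerance = 0.15)
  expect_gte(tc$K[1], raw$K[1])   # correction inflates counts near edges
})

test_that("planar vorticity is exact for a solid-body field and linear", {
  xs <- seq(-10, 10, by = 2); ys <- seq(-10, 10, by = 2)
  Omega <- 0.7
  u <- outer(xs, ys, function(x, y) -Omega * y)
  v <- outer(xs, ys, function(x, y) Omega * x)
  w <- planar_vorticity(u, v, 2)
  expect_equal(w, matrix(2 * Omega, length(xs), length(ys)))
  expect_equal(planar_vorticity(u * 0, v * 0, 2),
               matrix(0, length(xs), length(ys)))
  # linearity: vorticity of a sum is the sum of vorticities
  u2 <- outer(xs, ys, function(x, y) y^2); v2 <- outer(xs, ys, function(x, y) x)
  expect_equal(planar_vorticity(u + u2, v + v2, 2),
               w + planar_vorticity(u2, v2, 2), tolerance = 1e-12)
})

test_that("field export writes one tidy row per grid node", {
  xs <- seq(-4, 4, by = 2)
  fg <- structure(list(x = xs, y = xs, z_plane = 7,
                       u = outer(xs, xs, function(a, b) a),
                       v = outer(xs, xs, function(a, b) b),
                       omega_z = outer(xs, xs, function(a, b) 0 * a)),
                  class = "field_grid")
  f <- tempfile(fileext = ".csv")
  write_field_csv(fg, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), length(xs)^2)
  expect_equal(names(tab), c("x", "y", "z", "u", "v", "omega_z"))
  expect_equal(tab$u[tab$x == 2 & tab$y == -4], 2)
})

test_that("cycle-averaged fields converge in the number of phases", {
  sys <- cilia_system(list(rod_config()), beat_law(nodes_per_rod = 8L))
  f64 <- cycle_averaged_field(sys, z_plane = 7, xlim = c(-10, 10),
                              ylim = c(-10, 10), spacing = 4,
                              phases_per_cycle = 64L)
  f128 <- cycle_averaged_field(sys, z_plane = 7, xlim = c(-10, 10),
                               ylim = c(-10, 10), spacing = 4,
                               phases_per_cycle = 128L)
  ref <- max(sqrt(f128$u^2 + f128$v^2))
  expect_lt(max(abs(f64$u - f128$u), abs(f64$v - f128$v)) / ref, 0.01)
})
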
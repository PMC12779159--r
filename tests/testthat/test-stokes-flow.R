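# Regularized-Stokeslet hydrodynamics: blob, free-space kernel, wall
# images, force assembly, mobility solve.

test_that("blob evaluates to the closed form, decays, and has unit mass", {
  expect_equal(psi_blob(0, 0.1), 15 / (8 * pi * 1e-3), tolerance = 1e-12)
  r <- seq(0, 5, by = 0.01)
  v <- psi_blob(r, 0.1)
  expect_true(all(diff(v) < 0))
  expect_lt(psi_blob(100, 0.1), 1e-12)
  # radial quadrature oracle for the 3-space integral
  mass <- integrate(function(r) 4 * pi * r^2 * psi_blob(r, 0.1),
                    0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-8)
})

test_that("free-space kernel is linear in forces and matches the singular Stokeslet far away", {
  src <- random_stokeslets(5, seed = 2)
  pts <- matrix(runif(30, -5, 5), 10, 3)
  z <- src; z$forces <- z$forces * 0
  expect_equal(freespace_velocity(pts, z), matrix(0, 10, 3))
  d <- src; d$forces <- 2 * src$forces
  expect_equal(freespace_velocity(pts, d), 2 * freespace_velocity(pts, src))
  # r = 100 eps: relative error < 1e-3 against the singular closed form
  one <- stokeslet_set(matrix(c(0, 0, 3), 1), matrix(c(1.2, -0.4, 0.7), 1),
                       epsilon = 0.1)
  theta <- seq(0, 2 * pi, length.out = 17)[-17]
  far <- cbind(10 * cos(theta), 10 * sin(theta), 3 + 10 * sin(theta / 3))
  u <- freespace_velocity(far, one)
  us <- singular_stokeslet(far, c(0, 0, 3), c(1.2, -0.4, 0.7))
  expect_lt(max(abs(u - us)) / max(abs(us)), 1e-3)
})

test_that("wall velocity vanishes on the wall under random configurations", {
  src <- random_stokeslets(20, seed = 7)
  g <- seq(-20, 20, length.out = 50)
  wallpts <- cbind(rep(g, 50), rep(g, each = 50), 0)
  u0 <- wall_velocity(wallpts, src)
  u1 <- wall_velocity(cbind(wallpts[, 1:2], 1), src)
  expect_lt(max(abs(u0)), 1e-8 * max(abs(u1)))
})

test_that("the image system reduces to the singular image solution in the far field", {
  x0 <- c(0.5, -0.3, 2); f <- c(1.3, -0.7, 0.9)
  src <- stokeslet_set(matrix(x0, 1), matrix(f, 1), epsilon = 0.1)
  set.seed(11)
  pts <- cbind(runif(300, -30, 30), runif(300, -30, 30), runif(300, 0.5, 30))
  rsrc <- sqrt(rowSums(sweep(pts, 2, x0)^2))
  rimg <- sqrt(rowSums(sweep(pts, 2, c(x0[1], x0[2], -x0[3]))^2))
  keep <- rsrc >= 20 * 0.1 & rimg >= 20 * 0.1 & rsrc > 2.5
  pts <- pts[keep, ]
  u <- wall_velocity(pts, src)
  ub <- singular_blake(pts, x0, f)
  rel <- sqrt(rowSums((u - ub)^2)) / sqrt(rowSums(ub^2))
  expect_lt(max(rel), 1e-2)
})

test_that("near-wall flow decays faster laterally than the free-space Stokeslet", {
  src <- stokeslet_set(matrix(c(0, 0, 1), 1), matrix(c(1, 0, 0), 1), 0.1)
  pts <- cbind(seq(10, 40, by = 5), 0, 1)
  uw <- sqrt(rowSums(wall_velocity(pts, src)^2))
  uf <- sqrt(rowSums(freespace_velocity(pts, src)^2))
  ratio <- uw / uf
  expect_true(all(diff(ratio) < 0))   # image cancellation strengthens with r
  expect_lt(ratio[length(ratio)], 0.2)
})

test_that("mirror symmetry about y = 0 holds for the wall kernel", {
  pos <- matrix(c(1, 2, 3), 1); f <- matrix(c(0.5, -1.2, 0.8), 1)
  src <- stokeslet_set(pos, f, 0.1)
  posm <- pos; posm[, 2] <- -posm[, 2]
  fm <- f; fm[, 2] <- -fm[, 2]
  srcm <- stokeslet_set(posm, fm, 0.1)
  pts <- matrix(runif(30, -4, 4), 10, 3); pts[, 3] <- abs(pts[, 3])
  ptsm <- pts; ptsm[, 2] <- -ptsm[, 2]
  u <- wall_velocity(pts, src)
  um <- wall_velocity(ptsm, srcm)
  expect_equal(um[, 1], u[, 1], tolerance = 1e-12)
  expect_equal(um[, 2], -u[, 2], tolerance = 1e-12)
  expect_equal(um[, 3], u[, 3], tolerance = 1e-12)
})

test_that("wall solution approaches free space when the source is far above the wall", {
  # image corrections scale like (near-source distance) / height
  src <- stokeslet_set(matrix(c(0, 0, 2000), 1), matrix(c(1, -2, 0.5), 1),
                       0.1)
  set.seed(3)
  pts <- sweep(matrix(rnorm(60, sd = 2), 20, 3), 2, c(0, 0, 2000), "+")
  u <- wall_velocity(pts, src)
  uf <- freespace_velocity(pts, src)
  expect_lt(max(abs(u - uf)) / max(abs(uf)), 1e-3)
})

test_that("the velocity field is numerically divergence free", {
  src <- random_stokeslets(6, seed = 5)
  set.seed(6)
  base <- cbind(runif(60, -6, 6), runif(60, -6, 6), runif(60, 0.5, 6))
  hstep <- 0.05
  div <- numeric(nrow(base)); gmag <- numeric(nrow(base))
  for (k in 1:3) {
    dp <- base; dp[, k] <- dp[, k] + hstep
    dm <- base; dm[, k] <- dm[, k] - hstep
    dd <- (wall_velocity(dp, src) - wall_velocity(dm, src)) / (2 * hstep)
    div <- div + dd[, k]
    gmag <- gmag + rowSums(abs(dd))
  }
  expect_lt(max(abs(div) / gmag), 1e-3)
})

test_that("force assembly: stationary rods exert no force; resistive forces scale with velocity", {
  pos <- matrix(c(0, 0, 1, 0, 0, 2, 0, 0, 3), 3, 3, byrow = TRUE)
  v0 <- matrix(0, 3, 3)
  fp <- flow_params(gamma = 2.5)
  s <- assemble_forces(pos, v0, fp)
  expect_equal(s$forces, v0)
  expect_equal(max(abs(flow_velocity(matrix(c(1, 1, 1), 1), s, fp))), 0)
  v <- matrix(rnorm(9), 3, 3)
  s1 <- assemble_forces(pos, v, flow_params(gamma = 1))
  expect_equal(s1$forces, v)
})

test_that("mobility mode reproduces the prescribed node velocities", {
  law <- beat_law(nodes_per_rod = 8L)
  off <- ciliaflow:::node_offsets(1.1, law)
  pos <- off$positions
  vel <- off$velocities * law$omega
  fp <- flow_params(forcing_mode = "mobility")
  src <- assemble_forces(pos, vel, fp)
  u <- flow_velocity(pos, src, fp)
  expect_lt(max(abs(u - vel)) / max(abs(vel)), 1e-6)
})

test_that("the pairwise coupling matrix is reciprocal", {
  src <- random_stokeslets(7, seed = 9)
  # free space: the blob-smoothed kernel is exactly self-adjoint
  Gf <- coupling_matrix(src$positions, src$positions, 0.1, wall = FALSE)
  expect_lt(max(abs(Gf - t(Gf))), 1e-15)
  # with the wall the blob is smoothed on one side only, so reciprocity
  # holds up to the O(epsilon^2 / h^2) smoothing residue
  G <- coupling_matrix(src$positions, src$positions, 0.1, wall = TRUE)
  expect_lt(max(abs(G - t(G))) / max(abs(G)), 1e-5)
})

test_that("batched evaluation equals per-point evaluation and is additive over sources", {
  src <- random_stokeslets(8, seed = 4)
  pts <- cbind(runif(6, -5, 5), runif(6, -5, 5), runif(6, 0, 5))
  ub <- wall_velocity(pts, src)
  one_by_one <- t(vapply(seq_len(nrow(pts)), function(i)
    drop(wall_velocity(pts[i, , drop = FALSE], src)), numeric(3)))
  expect_equal(ub, one_by_one)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(wall_velocity(pts[perm, ], src), ub[perm, ])
  a <- stokeslet_set(src$positions[1:3, ], src$forces[1:3, ], 0.1)
  b <- stokeslet_set(src$positions[4:8, ], src$forces[4:8, ], 0.1)
  expect_equal(wall_velocity(pts, a) + wall_velocity(pts, b), ub,
               tolerance = 1e-12)
  expect_error(wall_velocity(matrix(c(0, 0, -1), 1), src), "below the wall")
})
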
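# Tissue geometries: single 3x3 cilia clusters, linear cluster arrays with
# variable spacing, random tissue patches of given ciliary density, and
# column-wise metachronal phase assignment.

#' Specification of a single cilia cluster
#'
#' A cluster is a regular 3 x 3 grid of cilia with intra-cluster spacing
#' `D`, so the cilia span `2 D` = 8 um on a side (the nominal footprint
#' that contains the cilia).  For spacing and overlap bookkeeping the
#' effective footprint is `3 D` on a side (three `D`-cells), under which
#' two clusters whose centres are `3 D` apart are exactly edge-to-edge.
#'
#' @param center Length-2 numeric, cluster centre in the wall plane (um).
#' @param D Intra-cluster rod spacing (um).
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(center = c(0, 0), D = 4) {
  stopifnot(length(center) == 2, D > 0)
  structure(list(center = as.numeric(center), D = D,
                 footprint = 2 * D, effective_footprint = 3 * D),
            class = "cluster_spec")
}

#' Build the nine rods of one cluster
#'
#' @param spec A [cluster_spec()].
#' @return List of 9 [rod_config()] objects on the regular lattice
#'   `center + \{-D, 0, D\} x \{-D, 0, D\}`, all with phase offset 0.
#' @export
build_cluster <- function(spec = cluster_spec()) {
  g <- c(-spec$D, 0, spec$D)
  rods <- list()
  for (gx in g) for (gy in g)
    rods[[length(rods) + 1]] <-
      rod_config(base = c(spec$center[1] + gx, spec$center[2] + gy))
  rods
}

#' Specification of a linear array of three clusters
#'
#' @param spacing_Dc Centre-to-centre cluster spacing (um); must be at
#'   least `3 D` so the effective cluster footprints do not interpenetrate.
#' @param D Intra-cluster rod spacing (um).
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(spacing_Dc = 3 * 4, D = 4) {
  stopifnot(D > 0)
  if (spacing_Dc < 3 * D)
    stop("spacing_Dc below 3*D: clusters would interpenetrate")
  structure(list(n_clusters = 3L, spacing_Dc = spacing_Dc, D = D),
            class = "array_spec")
}

#' Build a linear array of three clusters along x
#'
#' Clusters are centred at `x = -Dc, 0, +Dc` on the x-axis (the airway
#' axis); clearance transport is towards negative x.
#'
#' @param spec An [array_spec()].
#' @return List of 27 [rod_config()] objects (attribute `cluster_id`
#'   labels each rod 1..3).
#' @export
build_array <- function(spec = array_spec()) {
  centers <- c(-spec$spacing_Dc, 0, spec$spacing_Dc)
  rods <- list()
  ids <- integer(0)
  for (k in seq_along(centers)) {
    cl <- build_cluster(cluster_spec(center = c(centers[k], 0), D = spec$D))
    rods <- c(rods, cl)
    ids <- c(ids, rep(k, length(cl)))
  }
  attr(rods, "cluster_id") <- ids
  rods
}

#' Specification of a random tissue patch
#'
#' Cluster centres are sampled uniformly over the admissible region of an
#' `Lx x Ly` patch, rejecting placements closer than `min_separation`
#' (default `3 D` = 12 um, the effective footprint) to an accepted centre,
#' so footprints never overlap.  The target count is
#' `round(density * Lx * Ly / A_cluster)` with `A_cluster = (2 D)^2 =`
#' 64 um^2, the nominal area containing the cilia.
#'
#' @param Lx,Ly Patch side lengths (um).
#' @param density Ciliary density: fraction of the patch area covered by
#'   cluster footprints, in `(0, 0.7]`.
#' @param seed Integer seed making the placement reproducible.
#' @param D Intra-cluster rod spacing (um).
#' @param min_separation Minimum centre-to-centre distance (um).
#' @param max_attempts Cap on rejection-sampling draws.
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(Lx = 100, Ly = 100, density = 0.1, seed = 1L,
                       D = 4, min_separation = 3 * D,
                       max_attempts = 1e5) {
  stopifnot(Lx > 0, Ly > 0, density > 0, density <= 0.7, D > 0)
  structure(list(Lx = Lx, Ly = Ly, density = density,
                 seed = as.integer(seed), D = D,
                 min_separation = min_separation,
                 A_cluster = (2 * D)^2, max_attempts = max_attempts),
            class = "patch_spec")
}

#' Sample non-overlapping cluster positions for a tissue patch
#'
#' @param spec A [patch_spec()].
#' @return List of [cluster_spec()], one per placed cluster, with
#'   attribute `centers` (n x 2 matrix).  If the non-overlap constraint
#'   cannot be met within `max_attempts` draws a warning reports the
#'   achieved count.
#' @export
sample_patch <- function(spec = patch_spec()) {
  n_target <- round(spec$density * spec$Lx * spec$Ly / spec$A_cluster)
  # admissible centres keep the nominal 2D x 2D footprint inside the patch
  xr <- c(-spec$Lx / 2 + spec$D, spec$Lx / 2 - spec$D)
  yr <- c(-spec$Ly / 2 + spec$D, spec$Ly / 2 - spec$D)
  centers <- matrix(numeric(0), 0, 2)
  with_preserved_seed(spec$seed, {
    attempts <- 0
    while (nrow(centers) < n_target && attempts < spec$max_attempts) {
      attempts <- attempts + 1
      cand <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >=
              spec$min_separation))
        centers <- rbind(centers, cand)
    }
  })
  if (nrow(centers) < n_target)
    warning(sprintf("placed %d of %d clusters before hitting attempt cap",
                    nrow(centers), n_target))
  out <- lapply(seq_len(nrow(centers)), function(i)
    cluster_spec(center = centers[i, ], D = spec$D))
  rownames(centers) <- NULL
  attr(out, "centers") <- centers
  out
}

#' Build all rods of a sampled tissue patch
#'
#' @param clusters A list of [cluster_spec()] (from [sample_patch()]).
#' @return List of [rod_config()] with attribute `cluster_id`.
#' @export
build_patch <- function(clusters) {
  rods <- list()
  ids <- integer(0)
  for (k in seq_along(clusters)) {
    cl <- build_cluster(clusters[[k]])
    rods <- c(rods, cl)
    ids <- c(ids, rep(k, length(cl)))
  }
  attr(rods, "cluster_id") <- ids
  rods
}

#' Metachronal phase assignment
#'
#' Within each cluster the three columns of cilia (grouped by base x) get
#' phase offsets `0, phi0, 2 phi0` with x increasing, and cilia within a
#' column stay synchronized.  Positive `phi0` is the antiplectic
#' convention, negative symplectic.
#'
#' @param phase_increment Per-column phase lag \eqn{\phi_0} in radians.
#' @return An object of class `metachrony_spec`.
#' @export
metachrony_spec <- function(phase_increment = 0) {
  structure(list(phase_increment = as.numeric(phase_increment), axis = "x"),
            class = "metachrony_spec")
}

#' Apply column-wise metachronal phase offsets to rods
#'
#' Columns are ranked by base x and column `k` receives phase offset
#' `k * phi0`.  With `scope = "global"` (appropriate for x-aligned cluster
#' arrays) the ranking runs across all rods, so the lag accumulates from
#' cluster to cluster and the array carries one coherent wave; at
#' `phi0 = 2*pi/3` three columns accumulate a full `2*pi` and consecutive
#' clusters are back in phase.  With `scope = "cluster"` (used for random
#' tissue patches, whose clusters have no common column grid) the ranking
#' restarts inside each cluster.  Idempotent: offsets are set, not
#' accumulated.
#'
#' @param rods List of [rod_config()] with attribute `cluster_id` (as from
#'   [build_array()] or [build_patch()]; a bare cluster is treated as one
#'   cluster).
#' @param spec A [metachrony_spec()].
#' @param scope `"global"` or `"cluster"` column ranking.
#' @return The rod list with phase offsets assigned.
#' @export
assign_phases <- function(rods, spec = metachrony_spec(),
                          scope = c("global", "cluster")) {
  scope <- match.arg(scope)
  ids <- attr(rods, "cluster_id")
  if (is.null(ids)) ids <- rep(1L, length(rods))
  phi0 <- spec$phase_increment
  if (scope == "global") {
    xs <- round(vapply(rods, function(r) r$base[1], numeric(1)), 9)
    col <- match(xs, sort(unique(xs))) - 1L
    for (j in seq_along(rods))
      rods[[j]]$phase_offset <- col[j] * phi0
  } else {
    for (cl in unique(ids)) {
      idx <- which(ids == cl)
      xs <- round(vapply(rods[idx], function(r) r$base[1], numeric(1)), 9)
      col <- match(xs, sort(unique(xs))) - 1L  # 0, 1, 2 with increasing x
      for (j in seq_along(idx))
        rods[[idx[j]]]$phase_offset <- col[j] * phi0
    }
  }
  rods
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
  invisible(NULL)
}
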
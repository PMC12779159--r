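# Scenario configuration, orchestration, sweeps and persistence.

.scenario_kinds <- c("single_cluster", "three_clusters", "tissue_patch")

.known_keys <- list(
  top = c("kind", "beat", "flow", "geometry", "metachrony", "tracers",
          "integrator", "seeds", "output"),
  beat = c("omega", "theta_min", "theta_max", "L_fwd", "recovery_coeffs",
           "theta_shape", "nodes_per_rod"),
  flow = c("epsilon", "mu", "forcing_mode", "gamma", "wall"),
  geometry = c("D", "Dc_multiple", "Lx", "Ly", "density", "min_separation"),
  metachrony = c("phase_increment"),
  tracers = c("xlim", "ylim", "zlim", "n", "labeling", "breaks"),
  integrator = c("scheme", "steps_per_cycle", "duration_cycles",
                 "sample_every"))

#' Scenario configuration
#'
#' A fully-resolved, serializable description of one simulation: geometry,
#' beat parameters, flow parameters, metachrony, tracer seeding and
#' integration settings.  Unknown keys are rejected; all defaults are
#' resolved here so a run's output can embed the exact configuration.
#'
#' @param kind One of `"single_cluster"`, `"three_clusters"`,
#'   `"tissue_patch"`.
#' @param beat,flow,geometry,metachrony,tracers,integrator Named lists
#'   overriding the scenario defaults (see the package vignette).
#' @param seeds Integer vector of realization seeds (used by the tissue
#'   patch placement; deterministic scenarios run once per seed entry).
#' @return An object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config("single_cluster",
#'                        integrator = list(duration_cycles = 5),
#'                        tracers = list(n = 50))
#' @export
scenario_config <- function(kind = .scenario_kinds,
                            beat = list(), flow = list(), geometry = list(),
                            metachrony = list(), tracers = list(),
                            integrator = list(), seeds = 1L) {
  kind <- match.arg(kind)
  check_keys <- function(block, name) {
    bad <- setdiff(names(block), .known_keys[[name]])
    if (length(bad))
      stop(sprintf("unknown %s key(s): %s", name, paste(bad, collapse = ", ")))
    block
  }
  beat <- check_keys(beat, "beat")
  flow <- check_keys(flow, "flow")
  geometry <- check_keys(geometry, "geometry")
  metachrony <- check_keys(metachrony, "metachrony")
  tracers <- check_keys(tracers, "tracers")
  integrator <- check_keys(integrator, "integrator")

  geo_default <- switch(kind,
    single_cluster = list(D = 4),
    three_clusters = list(D = 4, Dc_multiple = 3),
    tissue_patch = list(D = 4, Lx = 100, Ly = 100, density = 0.1,
                        min_separation = 12))
  tr_default <- switch(kind,
    single_cluster = list(xlim = c(-20, 20), ylim = c(-20, 20),
                          zlim = c(1, 9), n = 500, labeling = "zband",
                          breaks = c(0, 3, 6, 9)),
    three_clusters = list(xlim = c(-50, 50), ylim = c(-50, 50),
                          zlim = c(5, 9), n = 1000, labeling = "x4",
                          breaks = NULL),
    tissue_patch = list(xlim = c(-50, 50), ylim = c(-50, 50),
                        zlim = c(5, 9), n = 2000, labeling = "x4",
                        breaks = NULL))
  cfg <- structure(list(
    kind = kind,
    beat = utils::modifyList(list(omega = 36 * pi, theta_min = 0.8,
                                  theta_max = 2.4, L_fwd = 7,
                                  recovery_coeffs = c(-0.3235, 5.2009,
                                                      -26.6650, 49.4710),
                                  theta_shape = "cosine2",
                                  nodes_per_rod = 15L), beat),
    flow = utils::modifyList(list(
      epsilon = 0.1, mu = 1,
      # clusters and arrays resolve cilia-cilia interaction (needed for
      # any phase-coordination effect on the mean flow); large patches
      # default to the cheaper resistive forcing
      forcing_mode = if (kind == "tissue_patch") "resistive" else "mobility",
      gamma = NULL, wall = TRUE), flow),
    geometry = utils::modifyList(geo_default, geometry),
    metachrony = utils::modifyList(list(phase_increment = 0), metachrony),
    tracers = utils::modifyList(tr_default, tracers),
    integrator = utils::modifyList(list(scheme = "rk4",
                                        steps_per_cycle = 100L,
                                        duration_cycles = 100L,
                                        sample_every = 1L), integrator),
    seeds = as.integer(seeds)), class = "scenario_config")
  # keep optional NULL-valued keys present and block order canonical so
  # configurations round-trip through YAML unchanged
  if (!("gamma" %in% names(cfg$flow))) cfg$flow["gamma"] <- list(NULL)
  if (!("breaks" %in% names(cfg$tracers))) cfg$tracers["breaks"] <- list(NULL)
  cfg$flow <- cfg$flow[.known_keys$flow]
  cfg$tracers <- cfg$tracers[.known_keys$tracers]
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: %s | %d cycle(s), %d seed(s)\n", x$kind,
              x$integrator$duration_cycles, length(x$seeds)))
  if (x$kind == "three_clusters")
    cat(sprintf("  Dc = %g D\n", x$geometry$Dc_multiple))
  if (x$kind == "tissue_patch")
    cat(sprintf("  %g x %g um patch, density %g\n",
                x$geometry$Lx, x$geometry$Ly, x$geometry$density))
  if (x$metachrony$phase_increment != 0)
    cat(sprintf("  metachronal phase lag phi0 = %.4g rad\n",
                x$metachrony$phase_increment))
  cat(sprintf("  tracers: %d (%s labels)\n", x$tracers$n,
              x$tracers$labeling))
  invisible(x)
}

#' Build the cilia system described by a configuration (one realization)
#'
#' @param config A [scenario_config()].
#' @param seed Realization seed (used by the tissue-patch placement).
#' @return A [cilia_system()].
#' @export
build_system <- function(config, seed = config$seeds[1]) {
  b <- config$beat
  law <- beat_law(omega = b$omega, theta_min = b$theta_min,
                  theta_max = b$theta_max, L_fwd = b$L_fwd,
                  recovery_coeffs = b$recovery_coeffs,
                  theta_shape = b$theta_shape,
                  nodes_per_rod = b$nodes_per_rod)
  fp <- flow_params(mu = config$flow$mu,
                    forcing_mode = config$flow$forcing_mode,
                    gamma = config$flow$gamma,
                    epsilon = config$flow$epsilon,
                    wall = config$flow$wall)
  g <- config$geometry
  rods <- switch(config$kind,
    single_cluster = build_cluster(cluster_spec(D = g$D)),
    three_clusters = build_array(array_spec(spacing_Dc = g$Dc_multiple * g$D,
                                            D = g$D)),
    tissue_patch = build_patch(sample_patch(patch_spec(
      Lx = g$Lx, Ly = g$Ly, density = g$density, seed = seed, D = g$D,
      min_separation = g$min_separation))))
  rods <- assign_phases(rods,
                        metachrony_spec(config$metachrony$phase_increment),
                        scope = if (config$kind == "tissue_patch")
                          "cluster" else "global")
  cilia_system(rods, law, fp)
}

#' Run one scenario
#'
#' Builds the system for each seed, seeds the tracers, advects them, and
#' returns the trajectory records together with the resolved
#' configuration.
#'
#' @param config A [scenario_config()].
#' @param verbose Print progress.
#' @return An object of class `scenario_run`: list with `config`,
#'   `systems`, `trajectories` (one per seed) and `elapsed` (seconds).
#' @export
run_scenario <- function(config, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  tr <- config$tracers
  tracers <- seed_tracers(list(xlim = tr$xlim, ylim = tr$ylim,
                               zlim = tr$zlim),
                          n = tr$n, labeling = tr$labeling,
                          breaks = tr$breaks)
  integ <- integrator_spec(scheme = config$integrator$scheme,
                           steps_per_cycle = config$integrator$steps_per_cycle,
                           duration_cycles = config$integrator$duration_cycles,
                           sample_every = config$integrator$sample_every)
  systems <- list(); trajs <- list()
  for (i in seq_along(config$seeds)) {
    if (verbose)
      message(sprintf("realization %d / %d (seed %d)", i,
                      length(config$seeds), config$seeds[i]))
    sys <- build_system(config, config$seeds[i])
    systems[[i]] <- sys
    trajs[[i]] <- advect(tracers, sys, integ, verbose = verbose)
  }
  structure(list(config = config, systems = systems, trajectories = trajs,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("Scenario run (%s): %d realization(s), %.1f s\n",
              x$config$kind, length(x$trajectories), x$elapsed))
  fin <- sapply(x$trajectories, final_displacement)
  cat(sprintf("  mean final displacement: dx=%.3f dy=%.3f dz=%.3f um\n",
              mean(fin[1, ]), mean(fin[2, ]), mean(fin[3, ])))
  invisible(x)
}

#' Simulate method for scenario configurations
#'
#' `simulate(cfg)` is equivalent to [run_scenario()]; `seed` overrides the
#' configuration's seed list.
#'
#' @param object A [scenario_config()].
#' @param nsim Number of realizations (seeds `seed + 0:(nsim-1)`).
#' @param seed Base seed; `NULL` keeps the configuration's seeds.
#' @param ... Passed to [run_scenario()].
#' @return A `scenario_run`.
#' @export
simulate.scenario_config <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) object$seeds <- as.integer(seed + seq_len(nsim) - 1)
  run_scenario(object, ...)
}

#' Parameter sweep over cluster spacing, phase lag or density
#'
#' Runs one scenario per parameter value (seeds held fixed) and tabulates
#' the final centre-of-mass displacement and, when tracer groups exist,
#' the final normalized mixing number.
#'
#' @param config Base [scenario_config()].
#' @param parameter `"Dc"` (spacing multiple, three-cluster scenario),
#'   `"phi0"` (metachronal lag, radians) or `"nu"` (density, tissue patch).
#' @param values Numeric vector of parameter values.
#' @param verbose Print progress.
#' @return An object of class `scenario_sweep`: list with `parameter`,
#'   `values`, `runs` and a summary data frame `table`.
#' @export
sweep_scenario <- function(config, parameter = c("Dc", "phi0", "nu"),
                           values, verbose = FALSE) {
  parameter <- match.arg(parameter)
  runs <- list()
  rows <- list()
  for (v in values) {
    cfg <- config
    if (parameter == "Dc") {
      stopifnot(cfg$kind == "three_clusters")
      cfg$geometry$Dc_multiple <- v
    } else if (parameter == "phi0") {
      cfg$metachrony$phase_increment <- v
    } else {
      stopifnot(cfg$kind == "tissue_patch")
      cfg$geometry$density <- v
    }
    if (verbose) message(sprintf("%s = %g", parameter, v))
    run <- run_scenario(cfg, verbose = verbose)
    runs[[length(runs) + 1]] <- run
    fin <- sapply(run$trajectories, final_displacement)
    mix <- NA_real_
    if (sum(table(run$trajectories[[1]]$labels) > 0) >= 2) {
      ms <- sapply(run$trajectories, function(tj) {
        s <- mixing_series(tj)
        s$m_over_m0[nrow(s)]
      })
      mix <- mean(ms)
    }
    rows[[length(rows) + 1]] <-
      data.frame(value = v, dx = mean(fin[1, ]), dy = mean(fin[2, ]),
                 dz = mean(fin[3, ]),
                 dx_sd = stats::sd(fin[1, ]), m_over_m0 = mix)
  }
  tab <- do.call(rbind, rows)
  names(tab)[1] <- parameter
  structure(list(parameter = parameter, values = values, runs = runs,
                 table = tab),
            class = "scenario_sweep")
}

#' @export
print.scenario_sweep <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d values)\n", x$parameter, length(x$values)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read / write scenario configurations as YAML
#'
#' @param file Path to a YAML file.
#' @return `read_scenario()` returns a [scenario_config()];
#'   `write_scenario()` returns `file` invisibly.
#' @export
read_scenario <- function(file) {
  y <- yaml::read_yaml(file)
  # YAML 1.1 parses a bare key `n` as the boolean FALSE; restore it
  y <- lapply(y, function(block) {
    if (is.list(block) && "FALSE" %in% names(block))
      names(block)[names(block) == "FALSE"] <- "n"
    block
  })
  bad <- setdiff(names(y), .known_keys$top)
  if (length(bad))
    stop("unknown top-level key(s): ", paste(bad, collapse = ", "))
  do.call(scenario_config, c(
    list(kind = y$kind %||% "single_cluster"),
    y[intersect(names(y), c("beat", "flow", "geometry", "metachrony",
                            "tracers", "integrator"))],
    if (!is.null(y$seeds)) list(seeds = y$seeds)))
}

#' @rdname read_scenario
#' @param config A [scenario_config()].
#' @export
write_scenario <- function(config, file) {
  yaml::write_yaml(unclass(config), file, precision = 15L)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a trajectory record as tidy CSV
#'
#' One row per snapshot and tracer: `cycle`, `tracer`, `label`, `x`, `y`,
#' `z`.
#'
#' @param traj A `tracer_trajectories`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectories_csv <- function(traj, file) {
  d <- dim(traj$positions)
  rows <- do.call(rbind, lapply(seq_len(d[1]), function(k)
    data.frame(cycle = traj$cycles[k], tracer = seq_len(d[2]),
               label = as.character(traj$labels),
               x = traj$positions[k, , 1], y = traj$positions[k, , 2],
               z = traj$positions[k, , 3])))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Export system geometry as CSV
#'
#' Columns `cluster_id`, `rod_id`, `x`, `y`, `phase_offset`.
#'
#' @param system A [cilia_system()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_geometry_csv <- function(system, file) {
  ids <- system$cluster_id
  if (is.null(ids)) ids <- rep(1L, length(system$rods))
  df <- data.frame(
    cluster_id = ids,
    rod_id = seq_along(system$rods),
    x = vapply(system$rods, function(r) r$base[1], numeric(1)),
    y = vapply(system$rods, function(r) r$base[2], numeric(1)),
    phase_offset = vapply(system$rods, function(r) r$phase_offset,
                          numeric(1)))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Summarize a run as JSON
#'
#' Writes final centre of mass, final normalized mixing number (when
#' groups exist) and the resolved configuration.
#'
#' @param run A `scenario_run`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_run_summary <- function(run, file) {
  fin <- sapply(run$trajectories, final_displacement)
  out <- list(kind = run$config$kind,
              seeds = run$config$seeds,
              final_com = list(dx = mean(fin[1, ]), dy = mean(fin[2, ]),
                               dz = mean(fin[3, ])),
              config = unclass(run$config))
  if (sum(table(run$trajectories[[1]]$labels) > 0) >= 2) {
    ms <- sapply(run$trajectories, function(tj) {
      s <- mixing_series(tj)
      s$m_over_m0[nrow(s)]
    })
    out$m_over_m0 <- mean(ms)
  }
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
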
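#' Scenario configuration
#'
#' Validates and completes a configuration for [run_scenario()]. Either give
#' a `preset` name (its geometry fills the remaining fields) or specify
#' `box`, `N` and `direction` explicitly. Validation failures name the
#' offending field.
#'
#' @param preset optional preset name, see [scenario_preset()].
#' @param box length-3 box (rc).
#' @param N polymer length.
#' @param direction `"x"` (parallel) or `"z"` (perpendicular).
#' @param force per-bead pulling force magnitude (m rc/tau^2), > 0.
#' @param aPH polymer-head adsorption amplitude (-5 weak, -20 strong).
#' @param replicas replica count (>= 1; at least 3 for reported statistics).
#' @param n_equil pre-equilibration steps with the pull off (default 500).
#' @param stride observation stride in steps (default 100 = 0.5 tau).
#' @param max_time wall clock of the pull stage in tau (safety cap on top of
#'   the termination rule).
#' @param rod_threshold,coil_threshold shape-factor thresholds for rod-coil
#'   transition detection.
#' @param dt,lambda integrator parameters.
#' @param area_per_lipid membrane packing (rc^2 per lipid per leaflet).
#' @param termination `"exit"` (direction-appropriate box-exit rule) or
#'   `"transition"` (stop once a rod-coil transition is complete; used by
#'   sweeps).
#' @param write_trajectory write an extended-XYZ trajectory per replica.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(preset = NULL, box = NULL, N = NULL,
                            direction = NULL, force = 2.0, aPH = -5,
                            replicas = 3L, n_equil = 500L, stride = 100L,
                            max_time = 1000, rod_threshold = 0.8,
                            coil_threshold = 0.3, dt = 0.005,
                            lambda = 0.65, area_per_lipid = 1.8,
                            termination = c("exit", "transition"),
                            write_trajectory = FALSE) {
  termination <- match.arg(termination)
  if (!is.null(preset)) {
    p <- scenario_preset(preset)
    if (is.null(box)) box <- p$box
    if (is.null(N)) N <- p$N
    if (is.null(direction)) direction <- p$direction
  }
  cfg <- list(preset = preset %||% "custom", box = box, N = N,
              direction = direction, force = force, aPH = aPH,
              replicas = as.integer(replicas),
              n_equil = as.integer(n_equil), stride = as.integer(stride),
              max_time = max_time, rod_threshold = rod_threshold,
              coil_threshold = coil_threshold, dt = dt, lambda = lambda,
              area_per_lipid = area_per_lipid, termination = termination,
              write_trajectory = isTRUE(write_trajectory))
  validate_scenario_config(cfg)
}

#' @rdname scenario_config
#' @param cfg a configuration list (e.g. from [read_config()]).
#' @export
validate_scenario_config <- function(cfg) {
  fail <- function(field, msg) stop("config$", field, ": ", msg,
                                    call. = FALSE)
  for (f in c("box", "N", "direction", "force", "aPH", "replicas"))
    if (is.null(cfg[[f]])) fail(f, "is required")
  if (length(cfg$box) != 3 || any(cfg$box <= 0))
    fail("box", "must be three positive lengths")
  if (cfg$N < 2) fail("N", "must be >= 2")
  if (!cfg$direction %in% c("x", "z"))
    fail("direction", "must be 'x' or 'z'")
  if (cfg$force <= 0) fail("force", "must be > 0")
  if (cfg$replicas < 1) fail("replicas", "must be >= 1")
  defaults <- list(preset = "custom", n_equil = 500L, stride = 100L,
                   max_time = 1000, rod_threshold = 0.8,
                   coil_threshold = 0.3, dt = 0.005, lambda = 0.65,
                   area_per_lipid = 1.8, termination = "exit",
                   write_trajectory = FALSE)
  cfg <- modifyList(defaults, cfg)
  if (!(cfg$rod_threshold > cfg$coil_threshold))
    fail("rod_threshold", "must exceed coil_threshold")
  if (!cfg$termination %in% c("exit", "transition"))
    fail("termination", "must be 'exit' or 'transition'")
  structure(cfg, class = "scenario_config")
}

config_to_preset <- function(cfg) {
  scenario_preset("custom", box = cfg$box, direction = cfg$direction,
                  force = cfg$force, aPH = cfg$aPH, N = cfg$N,
                  replicas = cfg$replicas,
                  area_per_lipid = cfg$area_per_lipid)
}

replica_seed <- function(seed, replica) {
  # double arithmetic: exact below 2^53, avoids 32-bit overflow for large
  # derived seeds; result always a valid 32-bit seed
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(replica)) %%
               2147483647)
}

#' Run one pulling scenario (build, equilibrate, pull, analyze)
#'
#' For each replica: assembles the system (replica-specific seed), writes
#' the manifest, pre-equilibrates with the pull off, finalises the
#' termination rule from the equilibrated chain's Rg0, runs the pull stage
#' with Rg / shape-factor / slab-count observers, detects the rod-coil
#' transition, and writes `observables.csv` plus `summary.json`. A
#' cross-replica `aggregate.json` is written at the top level.
#'
#' @param config a [scenario_config()] (or plain list; it is validated).
#' @param out_dir output directory (created; one subdirectory per replica).
#' @param seed integer master seed; replica seeds are derived from it.
#' @return Invisibly, a list with `replicas` (per-replica results) and
#'   `aggregate`.
#' @export
run_scenario <- function(config, out_dir, seed = 1L) {
  config <- validate_scenario_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reps <- vector("list", config$replicas)
  for (r in seq_len(config$replicas)) {
    rdir <- file.path(out_dir,
                      if (config$replicas > 1) sprintf("replica_%02d", r)
                      else ".")
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    reps[[r]] <- run_single_replica(config, rdir, replica_seed(seed, r), r)
  }
  trc <- aggregate_transition_periods(lapply(reps, `[[`, "transition"))
  aggregate <- list(preset = config$preset, direction = config$direction,
                    force = config$force, aPH = config$aPH,
                    replicas = config$replicas,
                    trc_mean = trc$trc_mean, trc_se = trc$trc_se,
                    trc_values = trc$values, n_detected = trc$n_detected,
                    pull_time_mean = mean(vapply(reps, `[[`, numeric(1),
                                                 "pull_time")))
  jsonlite::write_json(aggregate, file.path(out_dir, "aggregate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(replicas = reps, aggregate = aggregate))
}

run_single_replica <- function(config, rdir, rseed, replica) {
  manifest <- list(config = unclass(config), seed = rseed,
                   replica = replica,
                   package = "dpdpull",
                   version = as.character(packageVersion("dpdpull")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(rdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sc <- assemble_scenario(config_to_preset(config), seed = rseed)
  params <- integrator_params(dt = config$dt, lambda = config$lambda,
                              seed = rseed)
  state <- sc$state
  if (config$n_equil > 0)
    state <- dpd_steps(state, params, config$n_equil, protocol = NULL)
  rg0 <- radius_of_gyration(unwrap_chain(state))
  protocol <- sc$protocol
  if (config$termination == "transition") {
    protocol$termination <- termination_rule(
      "transition_detected", rod = config$rod_threshold,
      coil = config$coil_threshold, extra_time = 0)
  } else {
    protocol$termination$distance <-
      (if (config$direction == "x") state$box$lengths[1]
       else state$box$lengths[3]) - 2 * rg0
  }
  observers <- list(
    rg = function(s) radius_of_gyration(unwrap_chain(s)),
    delta = function(s) shape_factor(gyration_tensor(unwrap_chain(s))),
    nH = function(s) slab_head_count(s))
  t0 <- state$step * params$dt
  run <- dpd_run(state, params, protocol, observers,
                 n_steps = ceiling(config$max_time / config$dt),
                 stride = config$stride,
                 trajectory = if (config$write_trajectory)
                   file.path(rdir, "trajectory.xyz") else NULL)
  series <- run$series
  series$time <- series$time - t0 # pulling time from force-on
  write.csv(series, file.path(rdir, "observables.csv"), row.names = FALSE)
  trans <- detect_transition_period(series$time, series$delta,
                                    config$rod_threshold,
                                    config$coil_threshold)
  summary <- list(replica = replica, seed = rseed,
                  pull_time = max(series$time),
                  terminated = run$terminated, reason = run$reason,
                  rg0 = rg0, max_rg = max(series$rg),
                  max_delta = max(series$delta),
                  max_nH = max(series$nH),
                  trc = trans$trc, trc_detected = trans$detected)
  jsonlite::write_json(summary, file.path(rdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  c(summary, list(series = series, transition = trans))
}

#' Force-sweep specification
#'
#' @param forces per-bead force magnitudes; default 0.5 to 2.0 m rc/tau^2 in
#'   steps of 0.25.
#' @param aPH adsorption strengths to stratify over (default -5 and -20).
#' @param direction pulling axis.
#' @param replicas replicas per (force, aPH) cell, >= 1 (3 for reported
#'   mean errors).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(forces = seq(0.5, 2.0, by = 0.25), aPH = c(-5, -20),
                       direction = "z", replicas = 3L) {
  if (any(forces <= 0)) stop("forces must be > 0")
  if (replicas < 1) stop("replicas must be >= 1")
  structure(list(forces = forces, aPH = aPH, direction = direction,
                 replicas = as.integer(replicas)),
            class = "sweep_spec")
}

#' Run a force sweep and fit the exponential trc(F) trend
#'
#' Runs (or delegates to `runner`) one scenario per (force, aPH, replica),
#' extracts the rod-coil transition period from each shape-factor series,
#' aggregates replicas within each (force, aPH) cell — strata with different
#' aPH or direction are never mixed — and fits trc = A exp(-k F) per aPH
#' stratum. With fewer than three detected periods in a stratum the fit is
#' skipped with a warning and the table is still returned.
#'
#' @param sweep a [sweep_spec()].
#' @param base_config a [scenario_config()] supplying geometry and
#'   thresholds; its `force`, `aPH`, `direction` and `replicas` are
#'   overridden cell by cell.
#' @param out_dir optional output directory for `sweep.csv` and `fits.json`.
#' @param seed master seed.
#' @param runner function `(config, seed) -> data.frame(time, delta)`
#'   returning the shape-factor series of one replica; defaults to running
#'   the DPD engine. Injectable for testing and for post-hoc re-analysis.
#' @return List of class `sweep_result`: `table` (data.frame: aPH, force,
#'   trc_mean, trc_se, n_detected, n_replicas), `fits` (per-aPH
#'   [fit_exponential_decay()] or NULL).
#' @export
run_sweep <- function(sweep, base_config, out_dir = NULL, seed = 1L,
                      runner = NULL) {
  stopifnot(inherits(sweep, "sweep_spec"))
  if (is.null(runner)) runner <- engine_runner
  rows <- list()
  for (aph in sweep$aPH) for (fi in seq_along(sweep$forces)) {
    f <- sweep$forces[fi]
    periods <- vector("list", sweep$replicas)
    for (r in seq_len(sweep$replicas)) {
      cfg <- modifyList(unclass(base_config),
                        list(force = f, aPH = aph,
                             direction = sweep$direction, replicas = 1L,
                             termination = "transition"))
      cfg <- validate_scenario_config(cfg)
      cell_seed <- replica_seed(seed + 131L * fi + 7919L * match(aph, sweep$aPH), r)
      series <- runner(cfg, cell_seed)
      periods[[r]] <- detect_transition_period(series$time, series$delta,
                                               cfg$rod_threshold,
                                               cfg$coil_threshold)
    }
    agg <- aggregate_transition_periods(periods)
    rows[[length(rows) + 1L]] <-
      data.frame(aPH = aph, force = f, trc_mean = agg$trc_mean,
                 trc_se = agg$trc_se, n_detected = agg$n_detected,
                 n_replicas = sweep$replicas)
  }
  tab <- do.call(rbind, rows)
  fits <- lapply(split(tab, tab$aPH), function(s) {
    ok <- !is.na(s$trc_mean)
    if (sum(ok) < 3) {
      warning("aPH = ", s$aPH[1], ": fewer than 3 detected periods; ",
              "exponential fit skipped")
      return(NULL)
    }
    fit_exponential_decay(s$force[ok], s$trc_mean[ok])
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "sweep.csv"), row.names = FALSE)
    fit_json <- lapply(fits, function(f)
      if (is.null(f)) NULL else list(A = f$A, k = f$k))
    jsonlite::write_json(fit_json, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(table = tab, fits = fits), class = "sweep_result")
}

# default sweep runner: build + equilibrate + pull, return delta(t)
engine_runner <- function(config, seed) {
  res <- run_scenario(modifyList(unclass(config), list(replicas = 1L)),
                      out_dir = file.path(tempdir(),
                                          sprintf("sweep_%d", seed)),
                      seed = seed)
  res$replicas[[1]]$series[, c("time", "delta")]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<force sweep>\n")
  print(x$table, row.names = FALSE)
  for (nm in names(x$fits))
    if (!is.null(x$fits[[nm]]))
      cat(sprintf("  aPH=%s: A = %.4g tau, k = %.4g\n", nm,
                  x$fits[[nm]]$A, x$fits[[nm]]$k))
  invisible(x)
}
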
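#' Advance the dynamics by one or more steps
#'
#' Modified velocity-Verlet integration: position update
#' r <- r + dt v + dt^2/2 f, velocity prediction v~ <- v + lambda dt f, force
#' recomputation with the predicted velocities, then velocity correction
#' v <- v + dt/2 (f_old + f_new). One force evaluation per step (the
#' corrected force is cached in the state). Anchored beads never move and
#' keep zero velocity; positions are wrapped into the periodic box. Random
#' forces are keyed by the global step counter carried in the state, so a
#' run may be partitioned into calls arbitrarily without changing the
#' trajectory.
#'
#' @param state a [dpd_system()].
#' @param params an [integrator_params()].
#' @param n_steps number of steps to advance.
#' @param protocol optional [pull_protocol()]; its constant force is applied
#'   to the target beads during these steps.
#' @return The updated `dpd_system` (positions, velocities, cached forces,
#'   step counter).
#' @export
dpd_steps <- function(state, params, n_steps, protocol = NULL) {
  stopifnot(inherits(state, "dpd_system"), inherits(params, "integrator_params"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (n_steps == 0) return(state)
  if (is.null(protocol)) {
    pull <- c(0, 0, 0); targets <- integer()
  } else {
    pull <- protocol$force; targets <- as.integer(protocol$target) - 1L
  }
  b <- state$topology$bonds
  a <- state$topology$angles
  out <- dpd_run_cpp(
    state$positions, state$velocities, state$forces, type_codes(state),
    as.integer(state$anchored), unname(state$table$a), state$table$gamma,
    state$table$sigma, state$table$r_cut, state$box$lengths,
    cbind(as.integer(b$i) - 1L, as.integer(b$j) - 1L),
    as.numeric(b$ks), as.numeric(b$rs),
    cbind(as.integer(a$i) - 1L, as.integer(a$j) - 1L, as.integer(a$k) - 1L),
    as.numeric(a$ktheta), as.numeric(a$theta0),
    pull, targets, params$dt, params$lambda, as.numeric(params$seed),
    as.numeric(state$step), n_steps, cell_list = TRUE)
  state$positions <- out$positions
  state$velocities <- out$velocities
  state$forces <- out$forces
  state$step <- out$step
  state
}

#' @rdname dpd_steps
#' @export
integrate_step <- function(state, params, protocol = NULL) {
  dpd_steps(state, params, 1L, protocol)
}

#' Instantaneous kinetic temperature
#'
#' Mean kinetic energy per degree of freedom of the non-anchored beads,
#' kBT = sum(m v^2) / (3 n_free). For an equilibrated DPD fluid with
#' gamma = 4.5, sigma = 3.0 this fluctuates around sigma^2/(2 gamma) = 1.
#'
#' @param state a [dpd_system()].
#' @return Scalar kBT.
#' @export
kinetic_temperature <- function(state) {
  free <- !state$anchored
  if (!any(free)) stop("all beads are anchored; temperature is undefined")
  v <- state$velocities[free, , drop = FALSE]
  sum(state$mass[free] * rowSums(v^2)) / (3 * sum(free))
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Gaussian velocities at temperature `kBT` with the centre-of-mass drift of
#' the non-anchored beads removed; anchored beads get zero velocity.
#'
#' @param state a [dpd_system()].
#' @param kBT target temperature (default the table's implied kBT).
#' @param seed integer seed.
#' @return The state with fresh velocities.
#' @export
maxwell_velocities <- function(state, kBT = state$table$kBT, seed = 1L) {
  n <- nrow(state$positions)
  set.seed(seed)
  v <- matrix(rnorm(3 * n, sd = sqrt(kBT)), n, 3)
  free <- !state$anchored
  v[free, ] <- sweep(v[free, , drop = FALSE], 2, colMeans(v[free, , drop = FALSE]))
  v[!free, ] <- 0
  state$velocities <- v
  state$forces <- NULL
  state
}

#' Run dynamics with observers and a termination rule
#'
#' Advances the system in strides, evaluating each observer after every
#' stride and checking the protocol's termination rule. Observers are named
#' functions `f(state)` returning scalars; the results are collected into a
#' tidy series (one row per observation). The elapsed pulling time is
#' `step * dt` in tau.
#'
#' Centre-of-mass travel along the pull axis is accumulated from per-stride
#' minimum-image displacements of the target beads, so it is meaningful even
#' when the chain wraps around the periodic box.
#'
#' @param state a [dpd_system()].
#' @param params an [integrator_params()].
#' @param protocol optional [pull_protocol()] (NULL = no external force, rule
#'   `"none"`).
#' @param observers named list of functions `f(state) -> scalar`.
#' @param n_steps maximum number of steps.
#' @param stride steps between observations (default 100, i.e. 0.5 tau at
#'   dt = 0.005).
#' @param trajectory optional path; if set, frames are appended in extended
#'   XYZ format at every observation.
#' @return A list of class `dpd_run` with elements `state` (final), `series`
#'   (data.frame: step, time, observer columns, plus `com_travel` when a
#'   protocol is given), `terminated` (logical: rule fired before n_steps)
#'   and `reason`.
#' @export
dpd_run <- function(state, params, protocol = NULL, observers = list(),
                    n_steps, stride = 100L, trajectory = NULL) {
  stopifnot(inherits(state, "dpd_system"))
  n_steps <- as.integer(n_steps); stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1")
  rule <- if (is.null(protocol)) termination_rule("none") else
    protocol$termination
  target <- if (is.null(protocol)) integer() else protocol$target
  axis <- if (!is.null(protocol)) which(protocol$force != 0) else integer()
  if (length(axis) != 1) axis <- 3L

  observe <- function(s, travel) {
    vals <- vapply(observers, function(f) as.numeric(f(s)[1]), numeric(1))
    c(step = as.numeric(s$step), time = s$step * params$dt, vals,
      if (length(target)) c(com_travel = travel))
  }
  mi <- function(d, L) d - L * round(d / L)

  rows <- list()
  travel <- 0
  # COM travel accumulates mean per-bead minimum-image displacements per
  # stride (robust to individual beads wrapping across the boundary)
  prev_pos <- if (length(target)) state$positions[target, axis] else NULL
  rows[[1]] <- observe(state, travel)
  if (!is.null(trajectory))
    write_xyz(state, trajectory, time = state$step * params$dt,
              append = FALSE)
  done <- 0L
  terminated <- FALSE
  reason <- "n_steps"
  # transition bookkeeping
  rod_seen <- FALSE; coil_time <- NA_real_
  L_ax <- state$box$lengths[axis]
  while (done < n_steps) {
    k <- min(stride, n_steps - done)
    state <- dpd_steps(state, params, k, protocol)
    done <- done + k
    if (length(target)) {
      cur <- state$positions[target, axis]
      travel <- travel + mean(mi(cur - prev_pos, L_ax))
      prev_pos <- cur
    }
    rows[[length(rows) + 1L]] <- observe(state, travel)
    if (!is.null(trajectory))
      write_xyz(state, trajectory, time = state$step * params$dt,
                append = TRUE)
    tm <- state$step * params$dt
    fired <- switch(rule$rule,
      none = FALSE,
      parallel_exit = travel >= rule$distance,
      perpendicular_exit = {
        minz <- min(state$positions[target, 3])
        travel >= rule$distance &&
          minz > (rule$z_clear %||% 0)
      },
      transition_detected = {
        dlt <- shape_factor(gyration_tensor(
          unwrap_chain(state, target)))
        rod <- rule$rod %||% 0.8; coil <- rule$coil %||% 0.3
        if (!rod_seen && dlt >= rod) rod_seen <- TRUE
        if (rod_seen && is.na(coil_time) && dlt <= coil) coil_time <- tm
        !is.na(coil_time) && tm >= coil_time + (rule$extra_time %||% 0)
      })
    if (isTRUE(fired)) { terminated <- TRUE; reason <- rule$rule; break }
  }
  series <- as.data.frame(do.call(rbind, rows))
  structure(list(state = state, series = series, terminated = terminated,
                 reason = reason),
            class = "dpd_run")
}

#' @export
print.dpd_run <- function(x, ...) {
  cat(sprintf("<dpd_run: %d observations to t = %.2f tau (%s)>\n",
              nrow(x$series), max(x$series$time), x$reason))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
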
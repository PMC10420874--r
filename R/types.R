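#' Simulation box
#'
#' Rectangular box with per-axis lengths in rc units. All axes are periodic;
#' the origin sits at the box corner and z is measured from the substrate.
#'
#' @param lengths numeric length-3 vector `c(Lx, Ly, Lz)` in rc, all > 0.
#' @param periodic logical length-3; all axes must be periodic (the engine
#'   applies the minimum-image convention on every axis).
#' @return An object of class `box_spec`.
#' @examples
#' box_spec(c(20, 20, 40))
#' @export
box_spec <- function(lengths, periodic = c(TRUE, TRUE, TRUE)) {
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3 || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("box lengths must be three finite positive numbers")
  if (length(periodic) != 3 || !all(periodic))
    stop("all three axes must be periodic")
  structure(list(lengths = lengths, periodic = as.logical(periodic)),
            class = "box_spec")
}

#' @export
print.box_spec <- function(x, ...) {
  cat(sprintf("<box %g x %g x %g rc, periodic>\n",
              x$lengths[1], x$lengths[2], x$lengths[3]))
  invisible(x)
}

#' Conservative interaction table and thermostat coefficients
#'
#' Symmetric matrix of maximum conservative amplitudes a_ij (kBT/rc) over the
#' bead species P, W, H, T, together with the dissipative coefficient gamma,
#' the noise amplitude sigma, and the cutoff r_cut. The fluctuation-
#' dissipation relation sigma^2 = 2 gamma kBT fixes the thermostat
#' temperature; with the defaults gamma = 4.5, sigma = 3.0 this is kBT = 1.
#' Negative entries are permitted and model adsorption (e.g. a_PH < 0).
#'
#' @param a symmetric numeric matrix with dimnames over (a subset of)
#'   `c("P","W","H","T")`.
#' @param gamma dissipative (friction) coefficient.
#' @param sigma random-force amplitude.
#' @param r_cut interaction cutoff in rc, > 0.
#' @return An object of class `interaction_table` with an implied `kBT`
#'   component equal to `sigma^2 / (2 * gamma)`.
#' @seealso [default_interaction_table()]
#' @export
interaction_table <- function(a, gamma = 4.5, sigma = 3.0, r_cut = 1.0) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a) || is.null(rownames(a)) ||
      !identical(rownames(a), colnames(a)))
    stop("'a' must be square with matching row/column type names")
  if (!all(rownames(a) %in% BEAD_TYPES))
    stop("bead types must be among ", paste(BEAD_TYPES, collapse = ", "))
  if (max(abs(a - t(a))) > 1e-12) stop("'a' must be symmetric")
  if (!is.finite(r_cut) || r_cut <= 0) stop("r_cut must be > 0")
  if (gamma < 0 || sigma < 0) stop("gamma and sigma must be non-negative")
  kBT <- if (gamma > 0) sigma^2 / (2 * gamma) else 1
  structure(list(a = a, gamma = gamma, sigma = sigma, r_cut = r_cut,
                 kBT = kBT),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction table: gamma=%g sigma=%g r_cut=%g (kBT=%g)>\n",
              x$gamma, x$sigma, x$r_cut, x$kBT))
  print(x$a)
  invisible(x)
}

#' Bonded topology: harmonic bonds and angle-bending triplets
#'
#' Bonds carry the force F = ks (1 - r/rs) along the bond axis (zero at
#' r = rs, restoring on both sides); angles carry the potential
#' U = k_theta (theta - theta0)^2 on three consecutive beads.
#'
#' @param bonds data.frame with columns `i, j, ks, rs` (1-based bead indices;
#'   ks > 0, rs > 0). May have zero rows.
#' @param angles data.frame with columns `i, j, k, ktheta, theta0` (the angle
#'   is centred at `j`; ktheta >= 0, theta0 in (0, pi]). May have zero rows.
#' @param n_beads total bead count, for index range validation.
#' @return An object of class `bonded_topology`.
#' @export
bonded_topology <- function(bonds = empty_bonds(), angles = empty_angles(),
                            n_beads = NULL) {
  bonds <- as.data.frame(bonds)
  angles <- as.data.frame(angles)
  if (!all(c("i", "j", "ks", "rs") %in% names(bonds)))
    stop("bonds need columns i, j, ks, rs")
  if (!all(c("i", "j", "k", "ktheta", "theta0") %in% names(angles)))
    stop("angles need columns i, j, k, ktheta, theta0")
  if (nrow(bonds) && (any(bonds$ks <= 0) || any(bonds$rs <= 0)))
    stop("ks and rs must be positive")
  if (nrow(angles) && (any(angles$ktheta < 0) ||
                       any(angles$theta0 <= 0 | angles$theta0 > pi)))
    stop("ktheta must be >= 0 and theta0 in (0, pi]")
  if (!is.null(n_beads)) {
    idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k)
    if (length(idx) && (any(idx < 1) || any(idx > n_beads)))
      stop("bond/angle indices out of range")
  }
  if (nrow(bonds) && any(bonds$i == bonds$j))
    stop("a bond cannot join a bead to itself")
  if (nrow(angles) && any(angles$i == angles$j | angles$j == angles$k |
                          angles$i == angles$k))
    stop("angle triplets need three distinct beads")
  structure(list(bonds = bonds, angles = angles), class = "bonded_topology")
}

#' @rdname bonded_topology
#' @export
empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), ks = numeric(), rs = numeric())
}

#' @rdname bonded_topology
#' @export
empty_angles <- function() {
  data.frame(i = integer(), j = integer(), k = integer(),
             ktheta = numeric(), theta0 = numeric())
}

# concatenate topologies, shifting the second one's indices by `offset`
shift_topology <- function(topo, offset) {
  b <- topo$bonds; a <- topo$angles
  b$i <- b$i + offset; b$j <- b$j + offset
  a$i <- a$i + offset; a$j <- a$j + offset; a$k <- a$k + offset
  bonded_topology(b, a)
}

merge_topology <- function(t1, t2) {
  bonded_topology(rbind(t1$bonds, t2$bonds), rbind(t1$angles, t2$angles))
}

#' Constant-force pulling protocol
#'
#' A constant external force vector added to every target bead at every step.
#' Exactly one Cartesian component may be nonzero (pulling along x or z in
#' the membrane scenarios).
#'
#' @param target integer vector of 1-based bead indices (typically the whole
#'   polymer chain).
#' @param force either a length-3 numeric vector with exactly one nonzero
#'   component, or a scalar magnitude combined with `direction`.
#' @param direction `"x"`, `"y"` or `"z"`; used when `force` is scalar.
#' @param termination termination rule, see [termination_rule()].
#' @return An object of class `pull_protocol`.
#' @export
pull_protocol <- function(target, force, direction = NULL,
                          termination = termination_rule("none")) {
  target <- as.integer(target)
  if (length(force) == 1) {
    if (is.null(direction)) stop("scalar force needs a direction")
    ax <- match(direction, c("x", "y", "z"))
    if (is.na(ax)) stop("direction must be 'x', 'y' or 'z'")
    fv <- c(0, 0, 0); fv[ax] <- force
  } else {
    fv <- as.numeric(force)
    if (length(fv) != 3) stop("force must be scalar or length-3")
  }
  if (sum(fv != 0) > 1)
    stop("pull force must have exactly one nonzero component")
  structure(list(target = target, force = fv, termination = termination),
            class = "pull_protocol")
}

#' Termination rules for a single pulling process
#'
#' * `"none"`: run for the requested number of steps.
#' * `"parallel_exit"`: stop once the chain's centre of mass has travelled
#'   `distance` rc along the pull axis (default `Lx - 2 Rg0`, i.e. the chain
#'   has crossed the box).
#' * `"perpendicular_exit"`: stop once the lowest chain bead lies above
#'   `z_clear` (membrane top + cutoff) *and* the centre of mass has travelled
#'   `distance` rc along z.
#' * `"transition_detected"`: stop `extra_time` tau after a complete rod-coil
#'   transition of the chain's shape factor (up-crossing of `rod` followed by
#'   a down-crossing of `coil`); used by force sweeps that only need trc.
#'
#' @param rule one of `"none"`, `"parallel_exit"`, `"perpendicular_exit"`,
#'   `"transition_detected"`.
#' @param ... rule parameters: `distance`, `z_clear`, `rod`, `coil`,
#'   `extra_time`.
#' @return A list of class `termination_rule`.
#' @export
termination_rule <- function(rule = c("none", "parallel_exit",
                                      "perpendicular_exit",
                                      "transition_detected"), ...) {
  rule <- match.arg(rule)
  structure(c(list(rule = rule), list(...)), class = "termination_rule")
}

#' Integrator parameters
#'
#' Modified velocity-Verlet scheme: after the position update, velocities are
#' predicted as v + lambda * dt * f before the force recomputation, then
#' corrected with the trapezoidal average of old and new forces.
#'
#' @param dt time step in tau (> 0); default 0.005.
#' @param lambda velocity-prediction factor in (0, 1]; default 0.65, the
#'   standard empirical choice for rho = 3, gamma = 4.5 DPD fluids.
#' @param seed integer seed for the pairwise random forces.
#' @return An object of class `integrator_params`.
#' @export
integrator_params <- function(dt = 0.005, lambda = 0.65, seed = 1L) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(lambda) || lambda <= 0 || lambda > 1)
    stop("lambda must be in (0, 1]")
  structure(list(dt = dt, lambda = lambda, seed = as.integer(seed)),
            class = "integrator_params")
}

#' Complete simulation state
#'
#' Bundles bead positions/velocities/types, the bonded topology, the box, the
#' interaction table, anchored-bead flags, the cached force matrix, and the
#' global step counter. Metadata (`meta`) records builder provenance such as
#' the polymer bead indices, per-lipid head-bead indices, leaflet assignment
#' and the membrane top used by observables.
#'
#' @param positions n x 3 matrix, rc units, wrapped into the box.
#' @param velocities n x 3 matrix, rc/tau; anchored beads must have zero
#'   velocity.
#' @param types factor or character vector over `c("P","W","H","T")`.
#' @param box a [box_spec()].
#' @param table an [interaction_table()] covering all present types.
#' @param topology a [bonded_topology()].
#' @param anchored logical vector; anchored beads never move but still exert
#'   forces on their neighbours.
#' @param mass per-bead mass in units of m; the engine requires all 1.
#' @param meta named list of builder metadata.
#' @return An object of class `dpd_system`.
#' @export
dpd_system <- function(positions, velocities = NULL, types, box, table,
                       topology = bonded_topology(), anchored = NULL,
                       mass = NULL, meta = list()) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (ncol(positions) != 3 || any(!is.finite(positions)))
    stop("positions must be a finite n x 3 matrix")
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  if (!all(dim(velocities) == c(n, 3)) || any(!is.finite(velocities)))
    stop("velocities must be a finite n x 3 matrix")
  types <- factor(as.character(types), levels = BEAD_TYPES)
  if (length(types) != n || anyNA(types))
    stop("types must be length n over ", paste(BEAD_TYPES, collapse = ", "))
  if (!inherits(box, "box_spec")) stop("box must be a box_spec")
  if (!inherits(table, "interaction_table"))
    stop("table must be an interaction_table")
  present <- unique(as.character(types))
  if (!all(present %in% rownames(table$a)))
    stop("interaction table is missing type pair(s) for: ",
         paste(setdiff(present, rownames(table$a)), collapse = ", "))
  if (!inherits(topology, "bonded_topology"))
    stop("topology must be a bonded_topology")
  bonded_topology(topology$bonds, topology$angles, n_beads = n) # revalidate
  if (is.null(anchored)) anchored <- rep(FALSE, n)
  anchored <- as.logical(anchored)
  if (length(anchored) != n) stop("anchored must be length n")
  if (any(abs(velocities[anchored, , drop = FALSE]) > 0))
    stop("anchored beads must have zero velocity")
  if (is.null(mass)) mass <- rep(1, n)
  if (length(mass) != n || any(mass != 1))
    stop("the engine requires unit bead mass (m = 1)")
  # wrap into [0, L)
  for (d in 1:3)
    positions[, d] <- positions[, d] -
      box$lengths[d] * floor(positions[, d] / box$lengths[d])
  structure(list(positions = positions, velocities = velocities,
                 types = types, box = box, table = table,
                 topology = topology, anchored = anchored, mass = mass,
                 forces = NULL, step = 0, meta = meta),
            class = "dpd_system")
}

#' @export
print.dpd_system <- function(x, ...) {
  tt <- table(x$types)
  cat(sprintf("<dpd_system: %d beads (%s), box %g x %g x %g rc, step %d>\n",
              nrow(x$positions),
              paste(sprintf("%s=%d", names(tt), as.integer(tt)),
                    collapse = " "),
              x$box$lengths[1], x$box$lengths[2], x$box$lengths[3],
              as.integer(x$step)))
  cat(sprintf("  bonds: %d, angles: %d, anchored: %d\n",
              nrow(x$topology$bonds), nrow(x$topology$angles),
              sum(x$anchored)))
  invisible(x)
}

# integer type codes aligned with the interaction table's row order (0-based)
type_codes <- function(state) {
  match(as.character(state$types), rownames(state$table$a)) - 1L
}
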
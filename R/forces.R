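#' DPD weight function
#'
#' Linear weight w(r) = 1 - r/r_cut for r < r_cut and 0 beyond; continuous at
#' the cutoff. The conservative and random forces scale with w, the
#' dissipative force with w^2.
#'
#' @param r non-negative distance(s), rc units.
#' @param r_cut cutoff radius, > 0.
#' @return Numeric vector of weights in \[0, 1\].
#' @examples
#' dpd_weight(0.5, 1) # 0.5
#' @export
dpd_weight <- function(r, r_cut = 1.0) {
  if (any(r < 0)) stop("distances must be non-negative")
  if (!is.finite(r_cut) || r_cut <= 0) stop("r_cut must be > 0")
  ifelse(r < r_cut, 1 - r / r_cut, 0)
}

#' Pairwise DPD forces
#'
#' Sum of the conservative (a_ij w r_hat), dissipative
#' (-gamma w^2 (r_hat . v_ij) r_hat) and random
#' (sigma w zeta_ij dt^(-1/2) r_hat) contributions over all pairs within the
#' cutoff, under the minimum-image convention. The pair variates zeta_ij are
#' Gaussian with unit variance, symmetric (zeta_ij = zeta_ji), and are a pure
#' function of `(seed, counter, i, j)`, so evaluation order cannot change the
#' result. Newton's third law holds pairwise; beads separated by r >= r_cut
#' contribute nothing. Coincident beads (r < 1e-9 rc) receive the full
#' conservative amplitude along a deterministic pseudo-random direction and
#' no thermostat terms.
#'
#' @param state a [dpd_system()].
#' @param dt time step (enters the random force as dt^(-1/2)).
#' @param seed,counter integers keying the random variates; `counter` is the
#'   force-evaluation index (the engine uses the global step number).
#' @param cell_list use the O(N) cell-list path (default) or the all-pairs
#'   path; both give identical results.
#' @return n x 3 force matrix (anchored beads included; zeroing is applied by
#'   the integrator, not here).
#' @export
pair_forces <- function(state, dt = 0.005, seed = 0L, counter = 0L,
                        cell_list = TRUE) {
  pair_forces_cpp(state$positions, state$velocities, type_codes(state),
                  unname(state$table$a), state$table$gamma,
                  state$table$sigma, state$table$r_cut, state$box$lengths,
                  dt, as.numeric(seed), as.numeric(counter), cell_list)
}

#' Harmonic bond forces
#'
#' Per bond, bead i feels ks (1 - r_ij/rs) r_hat (r_hat pointing from j to
#' i) and bead j the opposite: zero at r = rs, attractive beyond, repulsive
#' below. Zero-length bonds follow the same degenerate-contact rule as the
#' pair forces (deterministic random direction, magnitude ks).
#'
#' @param state a [dpd_system()].
#' @return n x 3 force matrix.
#' @export
bond_forces <- function(state) {
  b <- state$topology$bonds
  bond_forces_cpp(state$positions, state$box$lengths,
                  cbind(as.integer(b$i) - 1L, as.integer(b$j) - 1L),
                  as.numeric(b$ks), as.numeric(b$rs))
}

#' Angle-bending forces
#'
#' Exact negative gradient of U = k_theta (theta - theta0)^2 with respect to
#' the three bead positions of each triplet; the net force and net torque of
#' every triplet vanish. Near-collinear configurations are regularised by
#' clamping cos(theta) to \[-1 + eps, 1 - eps\].
#'
#' @param state a [dpd_system()].
#' @return n x 3 force matrix.
#' @export
angle_forces <- function(state) {
  a <- state$topology$angles
  angle_forces_cpp(state$positions, state$box$lengths,
                   cbind(as.integer(a$i) - 1L, as.integer(a$j) - 1L,
                         as.integer(a$k) - 1L),
                   as.numeric(a$ktheta), as.numeric(a$theta0))
}

#' Angle-bending energy
#'
#' Total bending energy sum of k_theta (theta - theta0)^2 over the topology's
#' angle triplets (minimum-image bond vectors).
#'
#' @param state a [dpd_system()].
#' @return Scalar energy in kBT.
#' @export
angle_energy <- function(state) {
  a <- state$topology$angles
  if (!nrow(a)) return(0)
  L <- state$box$lengths
  pos <- state$positions
  mi <- function(d, Ld) d - Ld * round(d / Ld)
  tot <- 0
  for (t in seq_len(nrow(a))) {
    u <- mapply(mi, pos[a$i[t], ] - pos[a$j[t], ], L)
    v <- mapply(mi, pos[a$k[t], ] - pos[a$j[t], ], L)
    cth <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    cth <- min(max(cth, -1), 1)
    tot <- tot + a$ktheta[t] * (acos(cth) - a$theta0[t])^2
  }
  tot
}

#' Add a constant pulling force to target beads
#'
#' Adds the protocol's constant force vector to each target bead's row of the
#' force matrix; all other beads are untouched. An empty target set returns
#' the forces unchanged.
#'
#' @param forces n x 3 force matrix.
#' @param protocol a [pull_protocol()].
#' @return The updated force matrix.
#' @export
apply_pull <- function(forces, protocol) {
  if (length(protocol$target) == 0) return(forces)
  forces[protocol$target, ] <-
    sweep(forces[protocol$target, , drop = FALSE], 2, protocol$force, "+")
  forces
}
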
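# Small fixture systems and independent (plain-R) force oracles.

# a minimal two-bead system with explicit types/positions and a table whose
# thermostat can be switched off (sigma = 0 and/or gamma = 0)
two_bead_state <- function(pos_i, pos_j, types = c("W", "W"),
                           vel = matrix(0, 2, 3), box = c(10, 10, 10),
                           table = default_interaction_table(sigma = 0)) {
  dpd_system(rbind(pos_i, pos_j), vel, types, box_spec(box), table)
}

random_mixed_state <- function(n = 100, box_len = 6, seed = 1,
                              table = default_interaction_table()) {
  set.seed(seed)
  pos <- cbind(runif(n, 0, box_len), runif(n, 0, box_len),
               runif(n, 0, box_len))
  vel <- matrix(rnorm(3 * n, sd = 1), n, 3)
  types <- sample(c("P", "W", "H", "T"), n, replace = TRUE)
  dpd_system(pos, vel, types, box_spec(rep(box_len, 3)), table)
}

solvent_state <- function(box_len = 8, rho = 3, seed = 2, vseed = 3,
                          table = default_interaction_table()) {
  box <- box_spec(rep(box_len, 3))
  sol <- fill_solvent(box, rho, 0, seed = seed)
  st <- dpd_system(sol$positions, types = sol$types, box = box,
                   table = table)
  maxwell_velocities(st, seed = vseed)
}

# Independent all-pairs oracle for the deterministic force terms
# (conservative + dissipative; use sigma = 0 in the state's table when
# comparing against the engine). Written without the package's kernels.
oracle_pair_forces <- function(state) {
  pos <- state$positions; vel <- state$velocities
  L <- state$box$lengths
  a <- state$table$a
  gamma <- state$table$gamma; rc <- state$table$r_cut
  ty <- as.character(state$types)
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    d <- d - L * round(d / L)
    r <- sqrt(sum(d^2))
    if (r >= rc || r < 1e-9) next
    e <- d / r
    w <- 1 - r / rc
    f <- a[ty[i], ty[j]] * w - gamma * w^2 * sum(e * (vel[i, ] - vel[j, ]))
    F[i, ] <- F[i, ] + f * e
    F[j, ] <- F[j, ] - f * e
  }
  F
}

# central-difference gradient of an energy function of an n x 3 matrix
num_gradient <- function(energy, pos, h = 1e-6) {
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) for (d in 1:3) {
    pp <- pos; pp[i, d] <- pp[i, d] + h
    pm <- pos; pm[i, d] <- pm[i, d] - h
    g[i, d] <- (energy(pp) - energy(pm)) / (2 * h)
  }
  g
}
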
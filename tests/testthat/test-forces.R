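# Pair, bond and angle force kernels.

test_that("weight function is linear below the cutoff and zero beyond", {
  expect_equal(dpd_weight(0.5, 1.0), 0.5)
  expect_equal(dpd_weight(1.2, 1.0), 0.0)
  expect_equal(dpd_weight(1.0, 1.0), 0.0)
  expect_equal(dpd_weight(0, 1.0), 1.0)
  # continuity at the cutoff
  expect_lt(dpd_weight(1 - 1e-10, 1.0), 1e-9)
  expect_error(dpd_weight(-0.1, 1.0), "non-negative")
  expect_error(dpd_weight(0.5, 0), "r_cut")
})

test_that("conservative pair force has magnitude a_ij * w(r) along r_hat", {
  # two W beads (a = 25) at r = 0.5 rc, zero velocities, no noise
  st <- two_bead_state(c(5, 5, 5), c(5.5, 5, 5))
  F <- pair_forces(st, cell_list = FALSE)
  expect_equal(F[1, ], c(-12.5, 0, 0))
  expect_equal(F[2, ], c(12.5, 0, 0))

  # beyond the cutoff: zero total force
  st <- two_bead_state(c(5, 5, 5), c(6.5, 5, 5))
  expect_equal(pair_forces(st, cell_list = FALSE), matrix(0, 2, 3))

  # adsorption: P-H with a = -20 at r = 0.5 is attractive, magnitude 10
  st <- two_bead_state(c(5, 5, 5), c(5.5, 5, 5), types = c("P", "H"),
                       table = default_interaction_table(aPH = -20,
                                                         sigma = 0))
  F <- pair_forces(st, cell_list = FALSE)
  expect_equal(sqrt(sum(F[1, ]^2)), 10)
  expect_gt(F[1, 1], 0) # bead 1 is pulled toward bead 2
})

test_that("dissipative force damps the radial relative velocity", {
  # beads approaching head-on: v_ij . r_hat < 0, so the dissipative term
  # opposes the approach (adds repulsion along +x for bead 1)
  vel <- rbind(c(1, 0, 0), c(-1, 0, 0))
  st <- two_bead_state(c(5, 5, 5), c(5.5, 5, 5), vel = vel)
  F <- pair_forces(st, cell_list = FALSE)
  # conservative 12.5, dissipative -gamma w^2 (e.vij) = -4.5*0.25*(-2) = 2.25
  expect_equal(F[1, 1], -(12.5 + 2.25))
  expect_equal(F[2, 1], 12.5 + 2.25)
})

test_that("cell-list and all-pairs forces agree to 1e-10 with noise on", {
  for (seed in 1:3) {
    st <- random_mixed_state(n = 100, seed = seed)
    f_cell <- pair_forces(st, seed = 11, counter = 5, cell_list = TRUE)
    f_all <- pair_forces(st, seed = 11, counter = 5, cell_list = FALSE)
    expect_lt(max(abs(f_cell - f_all)), 1e-10)
  }
})

test_that("deterministic pair terms match an independent R oracle", {
  st <- random_mixed_state(n = 60, seed = 4,
                           table = default_interaction_table(sigma = 0))
  expect_equal(pair_forces(st), oracle_pair_forces(st), tolerance = 1e-12)
})

test_that("pair forces obey Newton's third law and cutoff locality", {
  st <- random_mixed_state(n = 80, seed = 7)
  F <- pair_forces(st, seed = 3, counter = 9)
  expect_lt(max(abs(colSums(F))), 1e-11)

  # perturbing a bead that is farther than r_cut from everyone (by
  # construction, periodic images included) changes no other bead's force
  set.seed(8)
  crowd <- matrix(runif(29 * 3, 1, 8), 29, 3)
  iso <- 30L
  pos <- rbind(crowd, c(15, 15, 15))
  st2 <- dpd_system(pos, types = rep("W", 30), box = box_spec(rep(20, 3)),
                    table = default_interaction_table(sigma = 0))
  F1 <- pair_forces(st2)
  st2$positions[iso, ] <- st2$positions[iso, ] + c(0.2, 0, 0)
  F2 <- pair_forces(st2)
  expect_equal(F1[-iso, ], F2[-iso, ])
  expect_equal(F1[iso, ], c(0, 0, 0))
})

test_that("pair random variates are symmetric and reproducible", {
  st <- random_mixed_state(n = 50, seed = 10)
  f1 <- pair_forces(st, seed = 42, counter = 17)
  f2 <- pair_forces(st, seed = 42, counter = 17)
  expect_identical(f1, f2)
  f3 <- pair_forces(st, seed = 42, counter = 18)
  expect_false(identical(f1, f3))
})

test_that("coincident beads get a finite deterministic conservative push", {
  st <- two_bead_state(c(5, 5, 5), c(5, 5, 5),
                       table = default_interaction_table())
  F1 <- pair_forces(st, seed = 1, counter = 1)
  F2 <- pair_forces(st, seed = 1, counter = 1)
  expect_identical(F1, F2)
  expect_true(all(is.finite(F1)))
  expect_equal(sqrt(sum(F1[1, ]^2)), st$table$a["W", "W"]) # magnitude a_ij
  expect_equal(F1[1, ], -F1[2, ])
})

test_that("bond force is restoring with magnitude ks|1 - r/rs|", {
  mk <- function(r, ks, rs) {
    topo <- bonded_topology(data.frame(i = 1, j = 2, ks = ks, rs = rs))
    dpd_system(rbind(c(5, 5, 5), c(5 + r, 5, 5)), types = c("P", "P"),
               box = box_spec(c(10, 10, 10)),
               table = default_interaction_table(), topology = topo)
  }
  expect_equal(bond_forces(mk(0.7, 120, 0.7)), matrix(0, 2, 3))
  expect_equal(bond_forces(mk(0.5, 200, 0.5)), matrix(0, 2, 3))
  F <- bond_forces(mk(0.35, 120, 0.7))
  expect_equal(abs(F[1, 1]), 60)
  expect_lt(F[1, 1], 0) # compressed: bead 1 pushed away from bead 2
  F <- bond_forces(mk(1.05, 120, 0.7))
  expect_equal(F[1, 1], 60) # stretched: bead 1 pulled toward bead 2
})

test_that("bond forces are the exact negative gradient of the potential", {
  # U(r) = ks/(2 rs) (r - rs)^2 gives F = ks (1 - r/rs) r_hat
  set.seed(5)
  pos <- matrix(runif(9, 2, 8), 3, 3)
  bonds <- data.frame(i = c(1, 2), j = c(2, 3), ks = c(120, 200),
                      rs = c(0.7, 0.5))
  st <- dpd_system(pos, types = rep("P", 3), box = box_spec(c(10, 10, 10)),
                   table = default_interaction_table(),
                   topology = bonded_topology(bonds))
  energy <- function(p) {
    e <- 0
    for (b in seq_len(nrow(bonds))) {
      r <- sqrt(sum((p[bonds$i[b], ] - p[bonds$j[b], ])^2))
      e <- e + bonds$ks[b] / (2 * bonds$rs[b]) * (r - bonds$rs[b])^2
    }
    e
  }
  expect_equal(bond_forces(st), -num_gradient(energy, pos),
               tolerance = 1e-6)
})

test_that("angle forces vanish at theta0 and match a finite-difference oracle", {
  mk <- function(pos, ktheta = 6, theta0 = 2 * pi / 3) {
    topo <- bonded_topology(
      angles = data.frame(i = 1, j = 2, k = 3, ktheta = ktheta,
                          theta0 = theta0))
    dpd_system(pos, types = rep("P", 3), box = box_spec(c(20, 20, 20)),
               table = default_interaction_table(), topology = topo)
  }
  # exactly at the equilibrium angle: zero force on all three beads
  p0 <- rbind(c(5, 5, 5), c(6, 5, 5),
              c(6 + cos(pi / 3), 5 + sin(pi / 3), 5))
  expect_lt(max(abs(angle_forces(mk(p0)))), 1e-9)

  # generic configuration: analytic gradient vs central differences
  set.seed(9)
  pos <- matrix(runif(9, 4, 7), 3, 3)
  st <- mk(pos)
  energy <- function(p) {
    u <- p[1, ] - p[2, ]; v <- p[3, ] - p[2, ]
    th <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    6 * (th - 2 * pi / 3)^2
  }
  expect_equal(angle_forces(st), -num_gradient(energy, pos),
               tolerance = 1e-6)
  # net force and net torque of the triplet are zero
  F <- angle_forces(st)
  expect_lt(max(abs(colSums(F))), 1e-10)
  torque <- colSums(t(vapply(1:3, function(i)
    c(pos[i, 2] * F[i, 3] - pos[i, 3] * F[i, 2],
      pos[i, 3] * F[i, 1] - pos[i, 1] * F[i, 3],
      pos[i, 1] * F[i, 2] - pos[i, 2] * F[i, 1]), numeric(3))))
  expect_lt(max(abs(torque)), 1e-9)
})

test_that("bending energy of a straight triplet with theta0 = 2pi/3 is k (pi/3)^2", {
  topo <- bonded_topology(
    angles = data.frame(i = 1, j = 2, k = 3, ktheta = 6, theta0 = 2 * pi / 3))
  st <- dpd_system(rbind(c(4, 5, 5), c(5, 5, 5), c(6, 5, 5)),
                   types = rep("P", 3), box = box_spec(c(10, 10, 10)),
                   table = default_interaction_table(), topology = topo)
  expect_equal(angle_energy(st), 6 * (pi / 3)^2, tolerance = 1e-9)
})

test_that("apply_pull adds the constant vector to targets only", {
  F <- matrix(0, 500, 3)
  p <- pull_protocol(1:500, 2.0, direction = "x")
  expect_equal(colSums(apply_pull(F, p)), c(1000, 0, 0))

  p0 <- pull_protocol(integer(), c(0, 0, 0.5))
  expect_equal(apply_pull(F, p0), F)

  sub <- c(3L, 7L, 11L)
  ps <- pull_protocol(sub, 0.5, direction = "z")
  Fs <- apply_pull(F, ps)
  expect_equal(Fs[sub, 3], rep(0.5, 3))
  expect_equal(sum(Fs != 0), 3)
})

test_that("a pull force must have exactly one nonzero component", {
  expect_error(pull_protocol(1:3, c(1, 0, 1)), "exactly one nonzero")
})
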
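# Gyration analysis, order parameters, slab counts, transition detection.

straight_rod <- function(N, b = 0.5) cbind(b * (seq_len(N) - 1), 0, 0)

test_that("radius of gyration: two-bead symmetry and the rod closed form", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))), 0.5)
  # b sqrt((N^2 - 1)/12) for an N-bead rod with spacing b
  for (N in 2:100) {
    rg <- radius_of_gyration(straight_rod(N))
    expect_equal(rg, 0.5 * sqrt((N^2 - 1) / 12), tolerance = 1e-9)
  }
  # 500 collinear beads at 0.5 rc spacing
  expect_equal(radius_of_gyration(straight_rod(500)), 72.17,
               tolerance = 1e-4)
})

test_that("gyration tensor: trace equals Rg^2, eigenvalues sorted and non-negative", {
  set.seed(21)
  for (rep in 1:5) {
    pos <- matrix(rnorm(30 * 3), 30, 3) %*% diag(c(3, 1, 0.2))
    g <- gyration_tensor(pos)
    expect_equal(sum(diag(g$tensor)), g$rg2, tolerance = 1e-10)
    expect_equal(g$rg2, radius_of_gyration(pos)^2, tolerance = 1e-10)
    expect_true(all(diff(g$eigenvalues) <= 0))
    expect_true(all(g$eigenvalues >= 0))
    expect_true(g$delta >= 0 && g$delta <= 1)
  }
})

test_that("gyration eigenvalues match a characteristic-polynomial oracle", {
  set.seed(33)
  pos <- matrix(runif(10 * 3, -2, 2), 10, 3)
  g <- gyration_tensor(pos)
  S <- g$tensor
  # det(S - x I) = -x^3 + tr x^2 - m2 x + det
  tr <- sum(diag(S))
  m2 <- sum(diag(S)[c(1, 1, 2)] * diag(S)[c(2, 3, 3)]) -
    S[1, 2]^2 - S[1, 3]^2 - S[2, 3]^2
  roots <- polyroot(c(det(S), -m2, tr, -1))
  expect_lt(max(abs(Im(roots))), 1e-8)
  expect_equal(sort(Re(roots), decreasing = TRUE), g$eigenvalues,
               tolerance = 1e-8)
})

test_that("shape factor: rod 1, isotropic 0, coincident 0, planar ring 1/4", {
  expect_equal(gyration_tensor(straight_rod(500))$delta, 1.0)
  # one nonzero eigenvalue for any collinear set
  expect_equal(sum(gyration_tensor(straight_rod(17))$eigenvalues > 1e-12), 1)

  iso <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(gyration_tensor(iso)$delta, 0)

  coincident <- matrix(2, 5, 3)
  g <- gyration_tensor(coincident)
  expect_equal(g$eigenvalues, c(0, 0, 0))
  expect_equal(g$delta, 0)

  th <- 2 * pi * (0:99) / 100
  ring <- cbind(cos(th), sin(th), 0)
  expect_equal(gyration_tensor(ring)$delta, 0.25, tolerance = 1e-10)
})

test_that("translating a molecule by lattice vectors leaves gyration invariant", {
  box <- box_spec(c(10, 10, 10))
  N <- 20
  topo <- bonded_topology(data.frame(i = 1:(N - 1), j = 2:N, ks = 200,
                                     rs = 0.5))
  set.seed(3)
  pos <- matrix(5, N, 3)
  for (m in 2:N) {
    u <- rnorm(3); pos[m, ] <- pos[m - 1, ] + 0.5 * u / sqrt(sum(u^2))
  }
  mk <- function(shift) {
    dpd_system(sweep(pos, 2, shift, "+"), types = rep("P", N), box = box,
               table = default_interaction_table(), topology = topo,
               meta = list(polymer = 1:N))
  }
  ref <- gyration_tensor(unwrap_chain(mk(c(0, 0, 0))))
  for (shift in list(c(10, 0, 0), c(0, -20, 0), c(10, 10, 10), c(7, 0, 0))) {
    g <- gyration_tensor(unwrap_chain(mk(shift)))
    expect_equal(g$rg2, ref$rg2, tolerance = 1e-10)
    expect_equal(g$delta, ref$delta, tolerance = 1e-10)
  }
})

test_that("unwrapping reconstructs a rod that crosses the boundary", {
  # 21-bead rod along x crossing x = 0: stored wrapped, Rg must match the
  # closed form after unwrapping
  N <- 21; b <- 0.5
  x <- (seq_len(N) - 1) * b + 8 # runs 8 .. 18 in a box of 10
  box <- box_spec(c(10, 10, 10))
  topo <- bonded_topology(data.frame(i = 1:(N - 1), j = 2:N, ks = 200,
                                     rs = b))
  st <- dpd_system(cbind(x %% 10, 5, 5), types = rep("P", N), box = box,
                   table = default_interaction_table(), topology = topo,
                   meta = list(polymer = 1:N))
  expect_equal(radius_of_gyration(unwrap_chain(st)),
               b * sqrt((N^2 - 1) / 12), tolerance = 1e-10)
})

test_that("order parameter limits: +z, in-plane, magic angle, isotropy", {
  expect_equal(order_parameter(c(0, 0, 1)), 1)
  expect_equal(order_parameter(c(1, 0, 0)), -0.5)
  expect_equal(order_parameter(c(0, 3, 0)), -0.5)
  th <- 54.7356 * pi / 180
  expect_equal(order_parameter(c(sin(th), 0, cos(th))), 0, tolerance = 1e-6)
  set.seed(11)
  v <- matrix(rnorm(3e4 * 3), 3e4, 3)
  expect_equal(order_parameter(v), 0, tolerance = 0.02)
  expect_error(order_parameter(c(0, 0, 0)), "zero")
})

synthetic_membrane_state <- function(n_lip, orient = "z", seed = 1,
                                     box_len = 80) {
  # three-bead head chains with controllable orientation, uniform lateral
  # placement; tails omitted (head metadata is what the profile uses)
  set.seed(seed)
  nh <- 3
  pos <- matrix(0, n_lip * nh, 3)
  H <- matrix(0L, n_lip, nh)
  for (l in seq_len(n_lip)) {
    base <- c(runif(1, 0, box_len), runif(1, 0, box_len), 5)
    dirv <- switch(orient,
      z = c(0, 0, 1),
      random = { u <- rnorm(3); u / sqrt(sum(u^2)) })
    for (m in seq_len(nh))
      pos[(l - 1) * nh + m, ] <- base + (m - 1) * 0.7 * dirv
    H[l, ] <- (l - 1L) * nh + seq_len(nh)
  }
  dpd_system(pos, types = rep("H", n_lip * nh),
             box = box_spec(rep(box_len, 3)),
             table = default_interaction_table(),
             meta = list(head_idx = H))
}

test_that("order-parameter profile: aligned heads give 1, random give ~0, empty bins NA", {
  st <- synthetic_membrane_state(4000, orient = "z", seed = 2)
  prof <- order_parameter_profile(st)
  expect_true(all(prof$P[prof$n_lipids > 0] == 1))

  st <- synthetic_membrane_state(16000, orient = "random", seed = 3)
  prof <- order_parameter_profile(st, bin_width = 10)
  expect_true(all(prof$n_lipids > 0))
  expect_true(all(abs(prof$P) < 0.05))

  # a region with no lipids: bins flagged NA, not 0
  st_small <- synthetic_membrane_state(10, orient = "z", seed = 4,
                                       box_len = 100)
  st_small$positions[, 1] <- st_small$positions[, 1] %% 10 # all at x < 10
  prof <- order_parameter_profile(st_small,
                                  region = list(x = c(20, 60), y = c(0, 100)))
  expect_true(all(is.na(prof$P)))
  expect_true(all(prof$n_lipids == 0))
})

test_that("order-parameter profile supports the end-to-end vector rule", {
  st <- synthetic_membrane_state(500, orient = "z", seed = 5)
  prof <- order_parameter_profile(st, vector_rule = "end_to_end")
  expect_true(all(prof$P[prof$n_lipids > 0] == 1))
})

test_that("slab head count uses a half-open interval over H beads only", {
  pos <- rbind(c(1, 1, 12), c(2, 2, 12), c(3, 3, 12), # H in slab
               c(4, 4, 15),                            # H at the top edge
               c(5, 5, 12),                            # W in slab: ignored
               c(6, 6, 9.99))                          # H below
  st <- dpd_system(pos, types = c("H", "H", "H", "H", "W", "H"),
                   box = box_spec(c(20, 20, 20)),
                   table = default_interaction_table())
  expect_equal(slab_head_count(st, 10, 15), 3)
  expect_equal(slab_head_count(st, 10, 15.01), 4)
  expect_error(slab_head_count(st, 15, 10), "z_lo")
})

test_that("upper-leaflet detachment fraction", {
  expect_equal(round(fraction_of_upper_leaflet(480, 79753), 1), 0.6)
  expect_equal(fraction_of_upper_leaflet(0, 1000), 0)
  expect_equal(fraction_of_upper_leaflet(500, 500), 100)
  expect_error(fraction_of_upper_leaflet(1, 0), "n0H")
})

test_that("transition period: square wave, monotone series, threshold order", {
  t <- seq(0, 40, by = 0.5)
  delta <- ifelse(t < 10, 0.1, ifelse(t < 25, 0.95, 0.1))
  res <- detect_transition_period(t, delta, 0.8, 0.3)
  expect_true(res$detected)
  expect_equal(res$trc, 15)

  mono <- detect_transition_period(t, seq(0, 1, length.out = length(t)),
                                   0.8, 0.3)
  expect_false(mono$detected)
  expect_true(is.na(mono$trc))

  none <- detect_transition_period(t, rep(0.5, length(t)), 0.8, 0.3)
  expect_false(none$detected)

  expect_error(detect_transition_period(t, delta, 0.3, 0.8), "exceed")
})

test_that("noisy synthetic pulses: width recovered within the replica mean error", {
  t <- seq(0, 60, by = 0.25)
  width <- 18
  set.seed(77)
  reps <- lapply(1:3, function(r) {
    delta <- ifelse(t >= 12 & t < 12 + width, 0.93, 0.12) +
      rnorm(length(t), sd = 0.03)
    detect_transition_period(t, delta, 0.8, 0.3)
  })
  agg <- aggregate_transition_periods(reps)
  expect_equal(agg$n_detected, 3)
  tol <- max(agg$trc_se, 0.25) # at least one sample stride
  expect_lt(abs(agg$trc_mean - width), 3 * tol + 1e-9)
})

test_that("exponential decay fit: exact recovery, constant case, equivariance, noise", {
  f <- seq(0.5, 2, by = 0.25)
  fit <- fit_exponential_decay(f, 100 * exp(-2 * f))
  expect_equal(unname(coef(fit)["A"]), 100, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["k"]), 2, tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-8)

  flat <- fit_exponential_decay(f, rep(42, length(f)))
  expect_equal(unname(coef(flat)["k"]), 0)
  expect_equal(unname(coef(flat)["A"]), 42)

  # scale equivariance: periods * c => A * c, k unchanged
  set.seed(13)
  per <- 80 * exp(-1.3 * f) * exp(rnorm(length(f), sd = 0.05))
  f1 <- fit_exponential_decay(f, per)
  f2 <- fit_exponential_decay(f, 10 * per)
  expect_equal(f2$A, 10 * f1$A, tolerance = 1e-10)
  expect_equal(f2$k, f1$k, tolerance = 1e-12)

  # 10% multiplicative noise, 7 points: rate within 20% of truth
  set.seed(29)
  noisy <- 100 * exp(-2 * f) * exp(rnorm(7, sd = 0.1))
  fitn <- fit_exponential_decay(f, noisy)
  expect_lt(abs(fitn$k - 2) / 2, 0.2)

  expect_error(fit_exponential_decay(c(1, 2), c(3, 4)), "three")
  expect_error(fit_exponential_decay(f, -f), "positive")
})

test_that("unit conversions follow the configured constants", {
  expect_equal(unclass(to_physical_units(1, "time")), 1.88,
               ignore_attr = TRUE)
  expect_equal(unclass(to_physical_units(2, "length")), 1.0,
               ignore_attr = TRUE)
  # m rc / tau^2 in pN from SI arithmetic
  expect_equal(force_unit_pN(),
               1.06e-23 * 0.5e-9 / (1.88e-9)^2 / 1e-12, tolerance = 1e-12)
  expect_equal(force_unit_pN(), 1.4996e-3, tolerance = 1e-4)
  f <- to_physical_units(2.0, "force")
  expect_equal(attr(f, "unit"), "pN")
  expect_equal(unclass(f), 2 * force_unit_pN(), ignore_attr = TRUE)
  # tau = rc sqrt(m / kBT) consistency: bead volume from rc = (rho Vb)^(1/3)
  u <- unit_system()
  expect_equal(u$bead_volume_nm3 * u$rho, u$rc_nm^3)
})
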
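#' Lipid architecture
#'
#' Coarse-grained lipid: one hydrophilic head chain of `n_head` H beads and
#' two hydrophobic tail chains of `n_tail` T beads each, joined at the
#' innermost head bead. Consecutive beads are bonded harmonically
#' (ks = 120, rs = 0.7 rc); three-consecutive-bead triplets within the head
#' chain and within each tail carry a bending potential with k_theta = 6 and
#' equilibrium angle `theta0_chain` (default pi, straight chains), while the
#' tail-head-tail triplet at the junction uses `theta0_junction`
#' (default 2 pi / 3, splayed tails).
#'
#' @param n_head head beads per lipid, >= 3.
#' @param n_tail tail beads per tail chain, >= 3 (two tails per lipid).
#' @param bond_ks,bond_rs bond parameters (kBT/rc^2, rc).
#' @param angle_k bending constant (kBT/rad^2).
#' @param theta0_chain,theta0_junction equilibrium angles (rad).
#' @return An object of class `lipid_architecture`.
#' @export
lipid_architecture <- function(n_head = 3, n_tail = 3, bond_ks = 120,
                               bond_rs = 0.7, angle_k = 6,
                               theta0_chain = pi,
                               theta0_junction = 2 * pi / 3) {
  if (n_head < 3 || n_tail < 3)
    stop("angle bending needs n_head >= 3 and n_tail >= 3")
  structure(list(n_head = as.integer(n_head), n_tail = as.integer(n_tail),
                 bond_ks = bond_ks, bond_rs = bond_rs, angle_k = angle_k,
                 theta0_chain = theta0_chain,
                 theta0_junction = theta0_junction),
            class = "lipid_architecture")
}

#' Membrane geometry specification
#'
#' @param area_per_lipid rc^2 per lipid per leaflet; the default 1.8 is
#'   calibrated so a full-scale 800 x 60 rc^2 upper leaflet carries about
#'   8.0e4 head beads with the 3-bead head chain.
#' @param z_center bilayer midplane height in rc (default 5, so the
#'   equilibrium membrane occupies roughly z = 1-9 rc above the substrate).
#' @param tail_gap vertical gap between the free tail ends of the two
#'   leaflets (rc).
#' @param tail_offset lateral offset of each tail from the head axis (rc).
#' @param jitter lateral lattice jitter amplitude as a fraction of the
#'   lattice spacing.
#' @return An object of class `membrane_spec`.
#' @export
membrane_spec <- function(area_per_lipid = 1.8, z_center = 5,
                          tail_gap = 0.5, tail_offset = 0.15,
                          jitter = 0.1) {
  stopifnot(area_per_lipid > 0, z_center > 0)
  structure(list(area_per_lipid = area_per_lipid, z_center = z_center,
                 tail_gap = tail_gap, tail_offset = tail_offset,
                 jitter = jitter),
            class = "membrane_spec")
}

#' Build a pre-formed bilayer membrane
#'
#' Places `floor(Lx * Ly / area_per_lipid)` lipids per leaflet on a jittered
#' rectangular lattice, tails pointing inward and head chains outward, and
#' anchors the bottom two head beads of every lower-leaflet lipid (the rigid
#' aqueous substrate: anchored beads never move but still interact). All
#' bond lengths equal rs at build time.
#'
#' @param box a [box_spec()].
#' @param arch a [lipid_architecture()].
#' @param spec a [membrane_spec()].
#' @param seed integer seed for the lattice jitter.
#' @return A bead group: list with `positions`, `types`, `anchored`,
#'   `topology`, and `meta` (`head_idx` matrix of per-lipid head-bead
#'   indices, `leaflet`, `n_lipids_per_leaflet`, `n0H` upper-leaflet head
#'   count, `membrane_top`).
#' @export
build_membrane <- function(box, arch = lipid_architecture(),
                           spec = membrane_spec(), seed = 1L) {
  L <- box$lengths
  n_lip <- floor(L[1] * L[2] / spec$area_per_lipid)
  if (n_lip < 1) stop("box is too small for a single lipid")
  nx <- max(1L, round(sqrt(n_lip * L[1] / L[2])))
  ny <- ceiling(n_lip / nx)
  sx <- L[1] / nx; sy <- L[2] / ny
  if (sx < 0.5 || sy < 0.5)
    stop("area_per_lipid too small: lattice spacing under 0.5 rc")
  nh <- arch$n_head; nt <- arch$n_tail
  rs <- arch$bond_rs; off <- spec$tail_offset
  if (off >= rs) stop("tail_offset must be smaller than the bond length")
  dz_att <- sqrt(rs^2 - off^2) # junction bond is exactly rs long
  per_lipid <- nh + 2L * nt
  # junction head-bead height (upper leaflet)
  z_j_up <- spec$z_center + spec$tail_gap / 2 + (nt - 1) * rs + dz_att

  set.seed(seed)
  site <- seq_len(n_lip) - 1L
  gx <- (site %% nx + 0.5) * sx
  gy <- (site %/% nx + 0.5) * sy
  build_leaflet <- function(upper) {
    x0 <- (gx + runif(n_lip, -spec$jitter, spec$jitter) * sx) %% L[1]
    y0 <- (gy + runif(n_lip, -spec$jitter, spec$jitter) * sy) %% L[2]
    sgn <- if (upper) 1 else -1
    z_j <- spec$z_center + sgn * (z_j_up - spec$z_center)
    pos <- matrix(0, n_lip * per_lipid, 3)
    for (l in seq_len(n_lip)) {
      o <- (l - 1L) * per_lipid
      # head chain: bead 1 outermost
      for (m in seq_len(nh))
        pos[o + m, ] <- c(x0[l], y0[l], z_j + sgn * (nh - m) * rs)
      for (tchain in 0:1) {
        xo <- if (tchain == 0) -off else off
        for (m in seq_len(nt))
          pos[o + nh + tchain * nt + m, ] <-
            c((x0[l] + xo) %% L[1], y0[l],
              z_j - sgn * (dz_att + (m - 1) * rs))
      }
    }
    pos
  }
  pos_up <- build_leaflet(TRUE)
  pos_lo <- build_leaflet(FALSE)
  positions <- rbind(pos_up, pos_lo)
  types <- rep(rep(c(rep("H", nh), rep("T", 2 * nt)), n_lip), 2)
  leaflet <- rep(c("upper", "lower"), each = n_lip * per_lipid)
  anchored <- rep(FALSE, nrow(positions))
  # bottom two head beads of each lower-leaflet lipid: local beads 1 and 2
  lo_off <- n_lip * per_lipid
  for (l in seq_len(n_lip))
    anchored[lo_off + (l - 1L) * per_lipid + 1:2] <- TRUE

  bonds <- vector("list", 2 * n_lip)
  angles <- vector("list", 2 * n_lip)
  for (leaf in 0:1) for (l in seq_len(n_lip)) {
    o <- leaf * lo_off + (l - 1L) * per_lipid
    hseq <- o + seq_len(nh)
    ta <- o + nh + seq_len(nt)
    tb <- o + nh + nt + seq_len(nt)
    bi <- c(hseq[-nh], hseq[nh], ta[-nt], hseq[nh], tb[-nt])
    bj <- c(hseq[-1], ta[1], ta[-1], tb[1], tb[-1])
    ai <- c(hseq[1:(nh - 2)], ta[1:(nt - 2)], tb[1:(nt - 2)], ta[1])
    aj <- c(hseq[2:(nh - 1)], ta[2:(nt - 1)], tb[2:(nt - 1)], hseq[nh])
    ak <- c(hseq[3:nh], ta[3:nt], tb[3:nt], tb[1])
    t0 <- c(rep(arch$theta0_chain, length(ai) - 1), arch$theta0_junction)
    bonds[[leaf * n_lip + l]] <-
      data.frame(i = bi, j = bj, ks = arch$bond_ks, rs = arch$bond_rs)
    angles[[leaf * n_lip + l]] <-
      data.frame(i = ai, j = aj, k = ak, ktheta = arch$angle_k, theta0 = t0)
  }
  topo <- bonded_topology(do.call(rbind, bonds), do.call(rbind, angles),
                          n_beads = nrow(positions))
  head_idx <- t(vapply(seq_len(2 * n_lip), function(g) {
    leaf <- (g - 1L) %/% n_lip
    l <- (g - 1L) %% n_lip + 1L
    as.integer(leaf * lo_off + (l - 1L) * per_lipid + seq_len(nh))
  }, integer(nh)))
  list(positions = positions, types = types, anchored = anchored,
       topology = topo,
       meta = list(head_idx = head_idx,
                   lipid_leaflet = rep(c("upper", "lower"), each = n_lip),
                   leaflet = leaflet,
                   n_lipids_per_leaflet = n_lip,
                   n0H = n_lip * nh,
                   membrane_top = max(pos_up[, 3]),
                   arch = arch, spec = spec))
}

#' Polymer chain specification
#'
#' @param N chain length in beads (>= 2; 500 at full scale).
#' @param ks,rs bond parameters (defaults 200 and 0.5 rc: stiff bonds that
#'   keep the chain linear under strong pulling).
#' @return An object of class `polymer_spec`.
#' @export
polymer_spec <- function(N = 500, ks = 200, rs = 0.5) {
  if (N < 2) stop("a chain needs at least two beads")
  structure(list(N = as.integer(N), ks = ks, rs = rs),
            class = "polymer_spec")
}

#' Build a surface-adsorbed polymer chain
#'
#' Random walk with exact step length rs, constrained to the slab
#' z in \[membrane_top, membrane_top + 2 rc\] just above the upper leaflet
#' (the z component of a step is flipped toward the interior when it would
#' leave the slab, preserving the step length) and wrapped periodically in
#' x and y. The chain is linear: N - 1 bonds, no angles.
#'
#' @param spec a [polymer_spec()].
#' @param membrane_top_z z of the membrane's upper head beads (rc).
#' @param box a [box_spec()].
#' @param seed integer seed; different seeds give different conformations
#'   with identical topology.
#' @param slab_height thickness of the placement slab (rc).
#' @return A bead group: list with `positions`, `types`, `anchored`,
#'   `topology`, `meta` (empty).
#' @export
build_polymer <- function(spec, membrane_top_z, box, seed = 1L,
                          slab_height = 2) {
  L <- box$lengths
  N <- spec$N; rs <- spec$rs
  z_lo <- membrane_top_z; z_hi <- membrane_top_z + slab_height
  if (z_hi > L[3]) stop("placement slab exceeds the box height")
  set.seed(seed)
  pos <- matrix(0, N, 3)
  pos[1, ] <- c(runif(1, 0, L[1]), runif(1, 0, L[2]),
                runif(1, z_lo + 0.25, z_hi - 0.25))
  for (m in 2:N) {
    # uniform direction on the sphere
    u <- rnorm(3); u <- u / sqrt(sum(u^2)) * rs
    z <- pos[m - 1, 3] + u[3]
    if (z < z_lo || z > z_hi) {
      u[3] <- -u[3]
      z <- pos[m - 1, 3] + u[3]
      if (z < z_lo || z > z_hi) u[3] <- 0 # cannot happen for slab > 2 rs
    }
    pos[m, ] <- pos[m - 1, ] + u
    pos[m, 1] <- pos[m, 1] %% L[1]
    pos[m, 2] <- pos[m, 2] %% L[2]
  }
  topo <- bonded_topology(
    data.frame(i = seq_len(N - 1), j = 2:N, ks = spec$ks, rs = spec$rs),
    n_beads = N)
  list(positions = pos, types = rep("P", N),
       anchored = rep(FALSE, N), topology = topo, meta = list())
}

#' Fill the box with solvent beads
#'
#' Adds water (W) beads at uniformly random positions so that the total bead
#' count equals `round(rho * Lx * Ly * Lz)` exactly. Soft DPD potentials
#' tolerate the resulting overlaps; a short pre-equilibration relaxes them.
#'
#' @param box a [box_spec()].
#' @param rho target bead number density (default 3).
#' @param occupied already-placed beads: a position matrix or a bead count.
#' @param seed integer seed (fill is deterministic under a fixed seed).
#' @return A bead group with the W beads.
#' @export
fill_solvent <- function(box, rho = 3, occupied = 0, seed = 1L) {
  if (rho <= 0) stop("rho must be positive")
  n_occ <- if (is.matrix(occupied)) nrow(occupied) else as.integer(occupied)
  n_total <- round(rho * prod(box$lengths))
  n_add <- n_total - n_occ
  if (n_add < 0)
    stop("target bead count ", n_total, " is below the ", n_occ,
         " already placed")
  set.seed(seed)
  pos <- cbind(runif(n_add, 0, box$lengths[1]),
               runif(n_add, 0, box$lengths[2]),
               runif(n_add, 0, box$lengths[3]))
  list(positions = pos, types = rep("W", n_add),
       anchored = rep(FALSE, n_add), topology = bonded_topology(),
       meta = list())
}

#' Default conservative interaction table
#'
#' Like-species repulsion 25 (W, H, T) and 15 (P); strong hydrophobic
#' incompatibility a_HT = a_WT = 100; hydrophilic compatibility a_WH = 25;
#' polymer-vs-other-species 50 (a_PW, a_PT); and the tunable polymer-head
#' adsorption a_PH (negative = attraction; -5 weak, -20 strong adsorption).
#' Thermostat gamma = 4.5, sigma = 3.0 (so kBT = 1), cutoff 1 rc.
#'
#' @param aPH polymer-head amplitude (kBT/rc).
#' @param a_PW,a_PT,a_WH,a_WT amplitudes left free by the membrane model;
#'   the defaults above are recorded in every run manifest.
#' @param gamma,sigma,r_cut thermostat coefficients and cutoff.
#' @return An [interaction_table()] over P, W, H, T.
#' @export
default_interaction_table <- function(aPH = -5, a_PW = 50, a_PT = 50,
                                      a_WH = 25, a_WT = 100, gamma = 4.5,
                                      sigma = 3.0, r_cut = 1.0) {
  a <- matrix(0, 4, 4, dimnames = list(BEAD_TYPES, BEAD_TYPES))
  a["P", "P"] <- 15
  a["W", "W"] <- a["H", "H"] <- a["T", "T"] <- 25
  a["H", "T"] <- a["T", "H"] <- 100
  a["P", "H"] <- a["H", "P"] <- aPH
  a["P", "W"] <- a["W", "P"] <- a_PW
  a["P", "T"] <- a["T", "P"] <- a_PT
  a["W", "H"] <- a["H", "W"] <- a_WH
  a["W", "T"] <- a["T", "W"] <- a_WT
  interaction_table(a, gamma = gamma, sigma = sigma, r_cut = r_cut)
}

#' Scenario presets
#'
#' Full-scale geometries (parallel pulling: 800 x 60 x 40 rc^3 box;
#' perpendicular pulling: 80 x 80 x 600 rc^3; N = 500) and scaled-down desk
#' presets (40 x 20 x 20 and 20 x 20 x 60 rc^3, N = 50, total beads <= 1e5)
#' that keep the same bead species, interaction table and protocol but are
#' only qualitative, trend-level stand-ins for the full boxes.
#'
#' @param name one of `"paper_parallel"`, `"paper_perpendicular"`,
#'   `"desk_parallel"`, `"desk_perpendicular"`, or `"custom"` (supply
#'   everything via `...`).
#' @param ... overrides: `box` (length-3 numeric), `direction` (`"x"`/`"z"`),
#'   `force` (per-bead magnitude, m rc/tau^2), `aPH`, `N`, `replicas`,
#'   `area_per_lipid`.
#' @return An object of class `scenario_preset`.
#' @export
scenario_preset <- function(name = c("desk_parallel", "desk_perpendicular",
                                     "paper_parallel", "paper_perpendicular",
                                     "custom"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    paper_parallel = list(box = c(800, 60, 40), direction = "x", N = 500L),
    paper_perpendicular = list(box = c(80, 80, 600), direction = "z",
                               N = 500L),
    desk_parallel = list(box = c(40, 20, 20), direction = "x", N = 50L),
    desk_perpendicular = list(box = c(20, 20, 60), direction = "z",
                              N = 50L),
    custom = list())
  p <- modifyList(c(list(name = name, force = 2.0, aPH = -5, replicas = 3L,
                         area_per_lipid = 1.8), base),
                  list(...))
  required <- c("box", "direction", "force", "aPH", "N", "replicas")
  missing <- setdiff(required, names(p))
  if (length(missing))
    stop("preset is missing field(s): ", paste(missing, collapse = ", "))
  if (!p$direction %in% c("x", "z"))
    stop("pulling direction must be 'x' or 'z'")
  if (length(p$box) != 3 || any(p$box <= 0)) stop("invalid box")
  if (p$replicas < 1) stop("replicas must be >= 1")
  structure(p, class = "scenario_preset")
}

#' Assemble a complete pulling scenario
#'
#' Builds membrane + polymer + solvent in the preset's box, draws
#' Maxwell-Boltzmann velocities at kBT = 1, and constructs the pulling
#' protocol (constant per-bead force on every polymer bead along the
#' preset's axis, with the direction-appropriate exit termination rule: the
#' travel distance `L_axis - 2 Rg0` is finalised by the pipeline after
#' equilibration).
#'
#' @param preset a [scenario_preset()] or preset name.
#' @param seed integer seed (controls membrane jitter, chain conformation,
#'   solvent placement and initial velocities).
#' @param arch a [lipid_architecture()].
#' @return List with `state` (a [dpd_system()]) and `protocol`
#'   (a [pull_protocol()]).
#' @export
assemble_scenario <- function(preset, seed = 1L,
                              arch = lipid_architecture()) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  box <- box_spec(preset$box)
  mspec <- membrane_spec(area_per_lipid = preset$area_per_lipid)
  mem <- build_membrane(box, arch, mspec, seed = seed)
  pol <- build_polymer(polymer_spec(N = preset$N), mem$meta$membrane_top,
                       box, seed = seed + 1L)
  n_mem <- nrow(mem$positions)
  n_pol <- nrow(pol$positions)
  sol <- fill_solvent(box, rho = 3, occupied = n_mem + n_pol,
                      seed = seed + 2L)
  positions <- rbind(mem$positions, pol$positions, sol$positions)
  types <- c(mem$types, pol$types, sol$types)
  anchored <- c(mem$anchored, pol$anchored, sol$anchored)
  topo <- merge_topology(mem$topology, shift_topology(pol$topology, n_mem))
  table <- default_interaction_table(aPH = preset$aPH)
  meta <- mem$meta
  meta$polymer <- n_mem + seq_len(n_pol)
  meta$preset <- preset$name
  state <- dpd_system(positions, types = types, box = box, table = table,
                      topology = topo, anchored = anchored, meta = meta)
  state <- maxwell_velocities(state, seed = seed + 3L)
  rg0 <- radius_of_gyration(unwrap_chain(state))
  axis_len <- if (preset$direction == "x") box$lengths[1] else box$lengths[3]
  term <- if (preset$direction == "x")
    termination_rule("parallel_exit", distance = axis_len - 2 * rg0)
  else
    termination_rule("perpendicular_exit", distance = axis_len - 2 * rg0,
                     z_clear = mem$meta$membrane_top + table$r_cut)
  protocol <- pull_protocol(meta$polymer, preset$force,
                            direction = preset$direction,
                            termination = term)
  list(state = state, protocol = protocol, preset = preset)
}
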
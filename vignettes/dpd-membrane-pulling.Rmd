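---
title: "DPD simulation of polymer chains pulled along and off lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DPD simulation of polymer chains pulled along and off lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdpull)
```

## The model

`dpdpull` simulates a linear bead-spring macromolecule interacting with a
solvent-supported phospholipid bilayer under a constant per-bead pulling
force, using dissipative particle dynamics (DPD). Four bead species appear:
polymer (P), water (W), lipid head (H) and lipid tail (T). All quantities
are in reduced units — length in the cutoff radius rc, energy in kBT, mass
in the bead mass m, and time in tau = rc * sqrt(m / kBT).

Every bead pair within the cutoff interacts through three forces:

* a soft conservative repulsion `a_ij * w(r) * r_hat` with the linear
  weight `w(r) = 1 - r/rc` (zero beyond the cutoff),
* a dissipative drag `-gamma * w(r)^2 * (r_hat . v_ij) * r_hat`,
* a random kick `sigma * w(r) * zeta_ij * dt^(-1/2) * r_hat` with
  unit-variance Gaussian `zeta_ij = zeta_ji`.

The last two form a momentum-conserving pairwise thermostat; the
fluctuation–dissipation relation `sigma^2 = 2 * gamma * kBT` with the
defaults gamma = 4.5, sigma = 3.0 fixes kBT = 1. Bonded beads feel the
harmonic force `ks * (1 - r/rs)` along the bond, and three consecutive
beads a bending potential `k_theta * (theta - theta0)^2`.

Lipids are `H3(T3)2`: a three-bead hydrophilic head chain and two
three-bead hydrophobic tails joined at the innermost head bead
(ks = 120, rs = 0.7 rc, k_theta = 6). Descriptions of this lipid
architecture commonly leave the junction bending geometry ambiguous;
this package defines it as: within-chain triplets are straight (theta0 = pi)
and the tail–head–tail triplet at the junction is splayed
(theta0 = 2*pi/3). Both are configurable in `lipid_architecture()`. The
polymer is a linear N-bead chain with stiff bonds (ks = 200, rs = 0.5 rc)
and no bending term.

The conservative amplitudes follow the standard membrane parameterisation:
like species 25 (W, H, T) and 15 (P), strong hydrophobic incompatibility
a_HT = a_WT = 100, hydrophilic compatibility a_WH = 25, and
polymer–membrane adsorption through a negative a_PH (-5 "weak", -20
"strong"). The membrane model does not by itself fix every cross-species
amplitude; the polymer–solvent and polymer–tail amplitudes default to
a_PW = a_PT = 50 (a strong polymer-vs-everything-else incompatibility).
All of these are arguments of `default_interaction_table()` and are
recorded in every run manifest.

## Integration and determinism

The engine uses the modified velocity-Verlet scheme standard in DPD:
position update, velocity prediction `v + lambda * dt * f`, force
recomputation, velocity correction with the trapezoidal force average. The
prediction factor lambda is a free parameter of the scheme; the package
defaults to lambda = 0.65, the common empirical choice for rho = 3,
gamma = 4.5 fluids, with dt = 0.005 tau. With these settings a pure
solvent box equilibrates to kinetic temperature 1.00 +/- 0.02 (the package
tests assert this).

Pair random variates are *counter-based*: `zeta_ij` at step s is a pure
hash of `(seed, s, min(i,j), max(i,j))` (splitmix64 mixing, Box–Muller
transform). Consequences worth knowing:

* trajectories are bitwise reproducible for a fixed seed,
* results do not depend on force-evaluation order or on how a run is
  partitioned into `dpd_steps()` calls,
* a checkpoint (`save_checkpoint()`) restarts exactly.

Neighbour search uses a cell list (edge >= rc) rebuilt every step — with
soft potentials and dt = 0.005 the per-step displacement is a small
fraction of rc, so no skin is needed. Boxes thinner than three cells per
axis fall back to the all-pairs path; both paths agree to machine
precision and the tests assert agreement to 1e-10.

Numerical edge cases are handled deterministically: exactly coincident
beads (r < 1e-9 rc, legal under soft potentials) receive the full
conservative amplitude along a hash-derived direction with the thermostat
terms skipped; near-collinear angles clamp cos(theta) away from +/-1;
non-finite coordinates abort with the offending bead and step.

Anchored beads (the substrate: the bottom two head beads of every
lower-leaflet lipid) never move and keep zero velocity, but their
interactions are computed so they repel and drag their neighbours; they are
excluded from the kinetic temperature.

## System construction

`build_membrane()` places `floor(Lx*Ly / area_per_lipid)` lipids per
leaflet on a jittered lattice, tails inward, heads outward, with every bond
at its rest length. The default area per lipid, 1.8 rc^2, is calibrated so
that the full-scale 800 x 60 rc^2 upper leaflet carries 79,998 head beads,
within 0.4% of the calibration target of ~79,753 heads; the bilayer midplane
sits at z = 5 rc so the equilibrium membrane occupies roughly z = 1–9 rc.
`build_polymer()` grows a random walk with exact step rs confined to a
2 rc slab above the upper leaflet. `fill_solvent()` tops the box up with
water beads so the total count equals `round(rho * V)` exactly at rho = 3;
initial solvent overlaps are legal and relax during the default 500-step
pre-equilibration that every pipeline run performs before switching the
pull on.

Two full-scale presets provide the full-size geometries
(`paper_parallel`: 800 x 60 x 40 rc^3 box, pull along x;
`paper_perpendicular`: 80 x 80 x 600 rc^3, pull along z; N = 500,
~5.8 million beads) and two desk presets (`desk_parallel` 40 x 20 x 20,
`desk_perpendicular` 20 x 20 x 60, N = 50, <= 1e5 beads) keep the same
species, interaction table and protocol at a tractable size.

## Observables

* `radius_of_gyration()` — Rg of the (periodically unwrapped) chain;
  `unwrap_chain()` walks the bond graph accumulating minimum-image
  displacements, so whole-box translations and boundary crossings do not
  affect any gyration quantity.
* `gyration_tensor()` / `shape_factor()` — the second-moment tensor about
  the centre of mass, its descending eigenvalues L1^2 >= L2^2 >= L3^2, and
  delta = 1 - 3(L1^2 L2^2 + L2^2 L3^2 + L3^2 L1^2) / (L1^2+L2^2+L3^2)^2.
  delta is 0 for an isotropic distribution and 1 for a rod. (Variants of
  this formula circulate with typographical errors; the standard symmetric
  form above is used. Under it an ideal planar ring scores 0.25,
  not the 0.5 sometimes quoted for "circular" conformations — quotes of
  0.5 rest on a circle definition that is never spelled out, so this
  package does not attempt to match it.)
* `order_parameter()` — P = <(3 cos^2 theta - 1)/2> of vectors against the
  +z membrane normal (1 aligned, -0.5 in-plane, 0 isotropic);
  `order_parameter_profile()` bins the per-lipid head-chain value along x
  (2 rc bins) inside the lateral interaction zone x, y in [20, 60) rc.
  The head-chain vector rule defaults to consecutive head-bead bonds
  averaged per lipid; an end-to-end rule is selectable. Empty bins are
  reported as NA, never as 0.
* `slab_head_count()` — the number nH of H beads in the half-open slab
  z in [10, 15) rc, which is empty for an intact membrane (z <= ~9) and
  counts detached lipids during pulling; `fraction_of_upper_leaflet()`
  converts it to a percentage of the upper-leaflet total n0H.
* `detect_transition_period()` — the rod–coil transition period trc: the
  time from the first up-crossing of the rod threshold by delta(t) to the
  subsequent down-crossing of the coil threshold. Thresholds are an
  analysis choice; the defaults 0.8 / 0.3 sit between the rod-like maxima
  (>= 0.87) and the relaxed coil values (~0.2) typical of strongly pulled
  N = 500 chains,
  and both are recorded per run. A series that never completes the cycle
  yields a flagged "not detected" result, not an error.
* `fit_exponential_decay()` — least squares of log(trc) on F, returning
  the amplitude A and rate k of trc = A exp(-k F).

## Unit mapping

`unit_system()` carries the reduced-to-physical mapping: rc = 0.5 nm,
tau = 1.88 ns, and m = 1.06e-23 kg (from coarse-graining a 5000 bp dsDNA
chain of 5.3e-21 kg into 500 beads). The force unit m rc/tau^2 computed
from these constants is 1.4996e-3 pN (`force_unit_pN()`); note that a
commonly quoted rounded value for the same mapping is 1.3e-3 pN — the
package always computes the conversion from the configured constants
rather than hard-coding either number, and this vignette records the
discrepancy rather than silently correcting it.

## What the desk-scale generator does and does not emulate

The full-scale geometries hold ~5.8 million beads; this package's tests
and example runs use 1e4–5e4 beads. The qualitative physics that survives
the scale-down, and is what the test suite asserts:

* an intact, tensionless bilayer over 1e4-step equilibrations
  (>= 95% of head beads stay within z = 0–10 rc),
* thermostat fidelity (kinetic temperature 1.00 +/- 0.02),
* adsorption of the chain onto the upper leaflet, lipid extraction into
  the z in [10, 15) slab during pulling, and membrane repair afterwards,
* chain stretching that grows with the pulling force.

Quantities that do *not* transfer quantitatively at desk scale: absolute
pulling times, peak Rg / delta / nH values, and the magnitude of the
rod–coil transition period. Three scale effects dominate. First, a short
chain (N ~ 50–100) on a small leaflet (~100–200 lipids) can extract the
entire contact patch of lipids and leave as a polymer–lipid blob instead
of peeling bead by bead, so the extended (rod) intermediate is much weaker
than for N = 500 on a 27,000-lipid leaflet. Second, the tension that
straightens the chain scales with the total applied force N*F, so desk
chains need proportionally larger per-bead forces to reach the same
tension regime. Third — and decisive for the rod–coil statistics — the
chain collapses in the strongly poor solvent into a globule whose shape
factor at the moment the pull switches on is a wide random variable
(delta(0) anywhere from ~0.05 to ~0.6 for N = 50), and whether a pulled
desk chain passes through a detectable rod state inherits that roll of the
dice: systematic per-seed series show the full phenomenology (delta up to
~0.94, transition periods decreasing from >25 tau at F = 1 to ~10 tau at
F = 3 per bead), but across seeds detection fails in roughly half of
replicas at every force examined. Reproducing the rod–coil transition
*reliably* therefore needs chain lengths of several hundred beads on a
proportionally large membrane — the full-scale presets. The dynamic
acceptance checks run the best-signal desk conditions with their problem
sizes stated in the test code, and their outcomes should be read with
this scale limitation in mind; the full-scale presets are provided for
machines with the memory and patience for them.

One quantitative reference value deserves a note. The commonly quoted
equilibrium coil size of the free N = 500 chain in this model family is
Rg = 3.2 rc. With this package's default interaction table the measured
plateau is
Rg ≈ 2.35 rc (box 13–15 rc^3, >150 tau): a_PW = 50 makes water a strongly
poor solvent, giving a dense globule, whereas 3.2 rc sits between the
ideal-coil value 4.56 rc and the globule value and would imply a milder
polymer–water repulsion. Because no complete interaction matrix pins a_PW down, the package
keeps the documented default rather than calibrating a_PW to reproduce
the quoted Rg; users who want the looser
coil can pass e.g. `default_interaction_table(a_PW = 30)` and re-measure.

## Design choices where the protocol was open

* **Stopping rule.** Pulling times in this kind of experiment are
  usually reported per force without a stated stopping criterion. The package defines a "single
  pulling process" as: parallel case — the chain's centre of mass has
  travelled `Lx - 2 Rg0` along x; perpendicular case — the lowest chain
  bead has cleared the membrane top by one cutoff *and* the centre of mass
  has travelled `Lz - 2 Rg0` (Rg0 measured after equilibration). Sweeps
  that only need trc may instead stop as soon as a rod–coil cycle
  completes (`termination = "transition"`).
* **Observation stride** defaults to 100 steps (0.5 tau) and
  **pre-equilibration** to 500 steps; both are configurable and recorded.
* **Coordinates** put the origin at the box corner with z measured from
  the substrate; all slab and region intervals are half-open [lo, hi).
* **Replica seeds** are derived deterministically from the master seed, so
  an entire multi-replica experiment is reproducible from one integer.

## Known limitations

* NVT only: no barostat or surface-tension coupling, so the membrane area
  per lipid is fixed by construction, not self-adjusted.
* No electrostatics and no explicit pH; adsorption strength is a single
  contact amplitude (a_PH).
* The membrane is built pre-formed; self-assembly from a random mixture is
  out of scope, as are multi-chain systems.
* Desk-scale results are trend-level stand-ins, as discussed above.
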
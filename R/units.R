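#' Reduced-to-physical unit mapping
#'
#' DPD reduced units: length rc, energy kBT, mass m, time
#' tau = rc sqrt(m / kBT). The default mapping follows coarse-graining a
#' 5000 bp dsDNA chain (total mass about 5.3e-21 kg) into N = 500 beads:
#' m = 1.06e-23 kg per bead, rc = 0.5 nm, tau = 1.88 ns. The cutoff is tied
#' to the bead density and volume through rc = (rho Vb)^(1/3), so
#' Vb = rc^3 / rho.
#'
#' With these constants the force unit is m rc / tau^2 =
#' 1.06e-23 kg * 0.5 nm / (1.88 ns)^2, which evaluates to about 1.5e-3 pN.
#' (A commonly quoted rounded value for the same mapping is 1.3e-3 pN; this
#' package always computes the conversion from the configured constants and
#' exposes it via [force_unit_pN()] rather than hard-coding either number.)
#'
#' @param rc_nm cutoff radius in nm (default 0.5).
#' @param tau_ns time unit in ns (default 1.88).
#' @param bead_mass_kg bead mass in kg (default 1.06e-23).
#' @param kBT_ref reference thermal energy in reduced units (default 1).
#' @param rho bead number density (default 3), used for Vb.
#' @return An object of class `unit_system`.
#' @export
unit_system <- function(rc_nm = 0.5, tau_ns = 1.88, bead_mass_kg = 1.06e-23,
                        kBT_ref = 1, rho = 3) {
  stopifnot(rc_nm > 0, tau_ns > 0, bead_mass_kg > 0, rho > 0)
  structure(list(rc_nm = rc_nm, tau_ns = tau_ns,
                 bead_mass_kg = bead_mass_kg, kBT_ref = kBT_ref, rho = rho,
                 bead_volume_nm3 = rc_nm^3 / rho),
            class = "unit_system")
}

#' @rdname unit_system
#' @param units a `unit_system`.
#' @return `force_unit_pN()`: the value of 1 m rc / tau^2 in pN.
#' @export
force_unit_pN <- function(units = unit_system()) {
  # kg * m / s^2 = N; 1 pN = 1e-12 N
  units$bead_mass_kg * (units$rc_nm * 1e-9) / (units$tau_ns * 1e-9)^2 / 1e-12
}

#' Convert a reduced quantity to physical units
#'
#' @param value numeric value(s) in reduced units (tau, m rc/tau^2, or rc).
#' @param kind `"time"`, `"force"` or `"length"`.
#' @param units a [unit_system()].
#' @return A `physical_quantity`: the converted numeric value with a `unit`
#'   attribute (`"ns"`, `"pN"`, `"nm"`).
#' @examples
#' to_physical_units(1, "time")   # 1.88 ns
#' to_physical_units(2, "length") # 1 nm
#' @export
to_physical_units <- function(value, kind = c("time", "force", "length"),
                              units = unit_system()) {
  kind <- match.arg(kind)
  out <- switch(kind,
    time = structure(value * units$tau_ns, unit = "ns"),
    length = structure(value * units$rc_nm, unit = "nm"),
    force = structure(value * force_unit_pN(units), unit = "pN"))
  class(out) <- "physical_quantity"
  out
}

#' @export
print.physical_quantity <- function(x, ...) {
  cat(paste(format(unclass(x)), attr(x, "unit")), sep = "\n")
  invisible(x)
}
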
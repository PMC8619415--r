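# Site-binding model of the electrolyte / native-oxide interface.
#
# The sensing surface carries amphoteric hydroxyl sites S-OH that can
# protonate (S-OH2+, acid constant Ka) or deprotonate (S-O-, base constant
# Kb).  Bulk pH sets the surface proton activity through the Boltzmann
# factor of the surface potential, and the ionized site populations set the
# oxide surface charge density that gates the transistor channel.

#' Native-oxide sensing surface
#'
#' Bundles the site-binding parameters of the oxide sensing layer.  Site
#' density is accepted in the customary sites/cm^2 and stored in SI
#' (sites/m^2); all downstream computation is SI.
#'
#' @param Ns_per_cm2 surface site density in sites/cm^2 (SiO2 default 5e12).
#' @param pKa acid dissociation exponent of the protonation reaction
#'   (S-OH2+ <-> S-OH + Hs+), dimensionless.
#' @param pKb base dissociation exponent of the deprotonation reaction
#'   (S-OH <-> S-O- + Hs+), dimensionless.
#' @param Ceq equivalent double-layer areal capacitance in F/m^2
#'   (default 0.2 F/m^2 = 20 uF/cm^2, a standard Gouy-Chapman-Stern
#'   magnitude).
#' @param T_K temperature in kelvin.
#' @param dpK_convention how the site-dissociation spread entering the
#'   surface buffer factor is formed: `"pKa_minus_pKb"` (default, the ISFET
#'   literature convention, = 8 for the SiO2 defaults) or `"pKb_minus_pKa"`.
#' @return An object of class `oxide_surface`.
#' @examples
#' ox <- oxide_surface()
#' point_of_zero_charge(ox)
#' @export
oxide_surface <- function(Ns_per_cm2 = 5e12, pKa = 6, pKb = -2,
                          Ceq = 0.2, T_K = 298.15,
                          dpK_convention = c("pKa_minus_pKb", "pKb_minus_pKa")) {
  dpK_convention <- match.arg(dpK_convention)
  stopifnot(is.numeric(Ns_per_cm2), length(Ns_per_cm2) == 1L, Ns_per_cm2 > 0,
            is.numeric(pKa), length(pKa) == 1L, is.finite(pKa),
            is.numeric(pKb), length(pKb) == 1L, is.finite(pKb))
  if (!is.numeric(Ceq) || length(Ceq) != 1L || Ceq <= 0)
    stop("'Ceq' must be a single positive capacitance in F/m^2", call. = FALSE)
  if (!is.numeric(T_K) || length(T_K) != 1L || T_K <= 0)
    stop("'T_K' must be a single positive temperature in kelvin", call. = FALSE)
  structure(
    list(Ns = Ns_per_cm2 * 1e4,   # sites/m^2
         Ns_per_cm2 = Ns_per_cm2,
         pKa = pKa, pKb = pKb,
         Ka = 10^(-pKa), Kb = 10^(-pKb),
         Ceq = Ceq, T_K = T_K,
         dpK_convention = dpK_convention),
    class = "oxide_surface")
}

#' @export
print.oxide_surface <- function(x, ...) {
  cat("oxide_surface (site-binding sensing layer)\n")
  cat(sprintf("  Ns   : %.3g sites/cm^2\n", x$Ns_per_cm2))
  cat(sprintf("  pKa  : %g   pKb: %g   pH_pzc: %g\n",
              x$pKa, x$pKb, point_of_zero_charge(x)))
  cat(sprintf("  Ceq  : %g F/m^2   T: %g K\n", x$Ceq, x$T_K))
  sf <- sensitivity_factor(x)
  cat(sprintf("  beta : %.4g   delta_w: %.4g\n", sf$beta, sf$delta_w))
  invisible(x)
}

#' Point of zero charge of the oxide surface
#'
#' The bulk pH at which the protonated and deprotonated site populations
#' balance and the net oxide surface charge vanishes: (pKa + pKb) / 2 in the
#' two-reaction site-binding model.
#'
#' @param surface an [oxide_surface()].
#' @return pH of zero charge (dimensionless).
#' @export
point_of_zero_charge <- function(surface) {
  stopifnot(inherits(surface, "oxide_surface"))
  (surface$pKa + surface$pKb) / 2
}

#' Surface buffer / sensitivity factors
#'
#' Computes the dimensionless intermediates of the site-binding response:
#' eta = 2 * 10^(-dpK/2) with dpK the site-dissociation spread, the
#' sensitivity parameter beta = q^2 * Ns * eta / (Ceq * kB * T), and the
#' Nernst-attenuation factor delta_w = beta / (beta + 1).  delta_w -> 1
#' recovers the Nernstian surface-potential slope.
#'
#' @param surface an [oxide_surface()].
#' @return A list with components `eta`, `beta`, `delta_w`.
#' @export
sensitivity_factor <- function(surface) {
  stopifnot(inherits(surface, "oxide_surface"))
  dpK <- switch(surface$dpK_convention,
                pKa_minus_pKb = surface$pKa - surface$pKb,
                pKb_minus_pKa = surface$pKb - surface$pKa)
  eta  <- 2 * 10^(-dpK / 2)
  beta <- .k_q^2 * surface$Ns * eta / (surface$Ceq * .k_kB * surface$T_K)
  list(eta = eta, beta = beta, delta_w = beta / (beta + 1))
}

#' Oxide surface potential at a given bulk pH
#'
#' Closed-form site-binding surface potential
#' psi0 = -ln(10) * delta_w * (kB*T/q) * (pH - pH_pzc).
#' At delta_w = 1 and 298.15 K the slope is the Nernst limit,
#' -59.16 mV per pH unit.
#'
#' @param pH bulk pH (vectorized).
#' @param surface an [oxide_surface()].
#' @return Surface potential psi0 in volts.
#' @export
surface_potential <- function(pH, surface) {
  stopifnot(inherits(surface, "oxide_surface"), is.numeric(pH))
  dw <- sensitivity_factor(surface)$delta_w
  -log(10) * dw * thermal_voltage(surface$T_K) *
    (pH - point_of_zero_charge(surface))
}

#' Surface hydrogen-ion activity
#'
#' Boltzmann relation between bulk and surface proton activity:
#' `[Hs+] = 10^(-pH) * exp(-q * psi0 / (kB * T))` in mol/L.
#'
#' @param pH bulk pH.
#' @param psi0 surface potential in volts.
#' @param T_K temperature in kelvin.
#' @return Surface proton activity in mol/L (strictly positive).
#' @export
surface_proton_activity <- function(pH, psi0, T_K = 298.15) {
  stopifnot(is.numeric(pH), is.numeric(psi0), T_K > 0)
  10^(-pH) * exp(-psi0 / thermal_voltage(T_K))
}

#' Oxide surface charge density
#'
#' Net areal charge of the ionized surface sites,
#' sigma0 = q * Ns * (Hs/Ka - Kb/Hs) / (Hs/Ka + Kb/Hs + 1),
#' bounded by +/- q*Ns and strictly increasing in the surface proton
#' activity Hs.  Acidic media protonate the surface (sigma0 > 0); basic
#' media deprotonate it (sigma0 < 0).
#'
#' @param Hs surface hydrogen-ion activity in mol/L (vectorized).
#' @param surface an [oxide_surface()].
#' @return Surface charge density sigma0 in C/m^2.
#' @export
surface_charge_density <- function(Hs, surface) {
  stopifnot(inherits(surface, "oxide_surface"), is.numeric(Hs))
  if (any(!is.finite(Hs)) || any(Hs <= 0))
    stop("'Hs' must be finite and strictly positive (mol/L)", call. = FALSE)
  a <- Hs / surface$Ka
  b <- surface$Kb / Hs
  .k_q * surface$Ns * (a - b) / (a + b + 1)
}

#' pH sweep of the interface state
#'
#' Chains [surface_potential()], [surface_proton_activity()] and
#' [surface_charge_density()] over a pH grid, producing the charge table
#' used as the gate boundary condition of the device model.
#'
#' @param pH_grid numeric vector of pH values in `[0, 14]`, non-empty.
#' @param surface an [oxide_surface()].
#' @return A data.frame with columns `pH`, `psi0_V`, `Hs_mol_per_L`,
#'   `sigma0_C_per_m2`, sorted by pH, one row per input value.
#' @export
ph_charge_table <- function(pH_grid, surface) {
  stopifnot(inherits(surface, "oxide_surface"))
  if (length(pH_grid) == 0L || !is.numeric(pH_grid))
    stop("'pH_grid' must be a non-empty numeric vector", call. = FALSE)
  if (any(pH_grid < 0 | pH_grid > 14))
    stop("'pH_grid' values must lie within [0, 14]", call. = FALSE)
  pH <- sort(pH_grid)
  psi0 <- surface_potential(pH, surface)
  Hs <- surface_proton_activity(pH, psi0, surface$T_K)
  sigma0 <- surface_charge_density(Hs, surface)
  data.frame(pH = pH, psi0_V = psi0, Hs_mol_per_L = Hs,
             sigma0_C_per_m2 = sigma0)
}
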
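# Physical constants (CODATA 2018, exact where the SI defines them).
.k_q    <- 1.602176634e-19   # elementary charge, C
.k_kB   <- 1.380649e-23      # Boltzmann constant, J/K
.k_eps0 <- 8.8541878128e-12  # vacuum permittivity, F/m
.k_NAv  <- 6.02214076e23     # Avogadro constant, 1/mol

#' Thermal voltage kB*T/q
#'
#' @param T_K temperature in kelvin.
#' @return Thermal voltage in volts (about 25.7 mV at 298.15 K).
#' @export
thermal_voltage <- function(T_K) {
  stopifnot(is.numeric(T_K), all(T_K > 0))
  .k_kB * T_K / .k_q
}
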
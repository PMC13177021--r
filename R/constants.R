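## Physical constants and unit conventions.
##
## Project-wide units: length nm, time ps, velocity nm/ps, energy kJ/mol,
## mass u (g/mol), charge e, temperature K, pressure bar.  With these,
## (g/mol) * (nm/ps)^2 = kJ/mol exactly, so kinetic energies need no
## conversion factor.

#' Molar gas constant in kJ/(mol K)
#' @keywords internal
.R_GAS <- 8.31446261815324e-3

#' Critical constants of water
#'
#' Critical temperature (K) and pressure (bar) of water, used to form the
#' reduced state coordinates Tr = T / Tc and Pr = P / Pc.
#'
#' @return Named numeric vector with elements `Tc` (647.096 K) and
#'   `Pc` (220.64 bar).
#' @examples
#' waterCriticalConstants()
#' @export
waterCriticalConstants <- function() {
  c(Tc = 647.096, Pc = 220.64)
}
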
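## Thermodynamic bookkeeping: reduced state coordinates and density errors.

#' Reduced temperature and pressure
#'
#' Maps an absolute state (T, P) to the dimensionless reduced coordinates
#' Tr = T / Tc, Pr = P / Pc with the critical constants of water
#' (Tc = 647.096 K, Pc = 220.64 bar).  Values are returned at full
#' precision; round for display.
#'
#' @param temperature temperature (K), > 0; vectorized
#' @param pressure pressure (bar), > 0; vectorized
#' @return named numeric vector (or 2-column matrix for vector input) with
#'   elements `Tr` and `Pr`
#' @examples
#' reducedState(679.451, 551.780)  # ~ (1.05, 2.50)
#' @export
reducedState <- function(temperature, pressure) {
  if (any(temperature <= 0) || any(pressure <= 0))
    stop("temperature and pressure must be positive")
  cc <- waterCriticalConstants()
  out <- cbind(Tr = temperature / cc[["Tc"]], Pr = pressure / cc[["Pc"]])
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Percent error of a simulated density
#'
#' @param densitySim simulated density (kg/m^3); vectorized
#' @param densityExp experimental reference density (kg/m^3), > 0
#' @return 100 * |sim - exp| / exp (percent)
#' @examples
#' densityPercentError(584.852, 581.043)  # 0.656 at 3 decimals
#' @export
densityPercentError <- function(densitySim, densityExp) {
  if (any(densityExp <= 0)) stop("densityExp must be positive")
  100 * abs(densitySim - densityExp) / densityExp
}

#' Reference simulation conditions table
#'
#' The bundled table of 15 supercritical simulation conditions (GROMACS
#' nominal temperature and pressure with simulated and NIST experimental
#' densities), shipped as plain CSV in \code{inst/extdata}.
#'
#' @return data.frame with columns condition, temperature_K, pressure_bar,
#'   density_sim_kgm3, density_exp_kgm3, error_pct (the tabulated percent
#'   deviation, reproducible via [densityPercentError()])
#' @export
simulationConditions <- function() {
  path <- system.file("extdata", "supercritical_conditions.csv",
                      package = "scwnet", mustWork = TRUE)
  utils::read.csv(path)
}
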
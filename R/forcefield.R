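## Force-field constructors and mass bookkeeping.

#' Default four-site water parameters (TIP4P/2005)
#'
#' The rigid four-site model used throughout: the Lennard-Jones center sits
#' on the oxygen, the negative charge on the massless M site displaced along
#' the H-O-H bisector, and the positive charge split over the hydrogens.
#' All values are overridable per call.
#'
#' @param qH hydrogen charge (e)
#' @param qM M-site charge (e)
#' @param sigmaOO O-O Lennard-Jones sigma (nm)
#' @param epsilonOO O-O Lennard-Jones epsilon (kJ/mol)
#' @param mH,mO site masses (g/mol)
#' @param rOH O-H bond length (nm)
#' @param thetaHOH H-O-H angle (degrees)
#' @param dOM O-M distance (nm)
#' @param fCoulomb Coulomb prefactor (kJ mol^-1 nm e^-2)
#' @return a validated [ForceField-class]
#' @examples
#' ff <- tip4p2005()
#' waterMass(ff)  # 18.01528 g/mol
#' @export
tip4p2005 <- function(qH = 0.5564, qM = -1.1128,
                      sigmaOO = 0.3159, epsilonOO = 0.7749,
                      mH = 1.00794, mO = 15.9994,
                      rOH = 0.09572, thetaHOH = 104.52, dOM = 0.01546,
                      fCoulomb = 138.935458) {
  new("ForceField",
    qH = qH, qM = qM, sigmaOO = sigmaOO, epsilonOO = epsilonOO,
    mH = mH, mO = mO, rOH = rOH, thetaHOH = thetaHOH, dOM = dOM,
    fCoulomb = fCoulomb)
}

#' Molecular mass of the water model
#' @param ff a [ForceField-class]
#' @return 2 m_H + m_O (g/mol)
#' @export
waterMass <- function(ff = tip4p2005()) 2 * ff@mH + ff@mO

## Mass-weighted COM over the massive sites of an [n, 3, 4] array
## (sites Ha, O, M, Hb; M massless).
.comPositions <- function(arr, ff) {
  m <- (ff@mH * arr[, , 1L, drop = FALSE] +
        ff@mO * arr[, , 2L, drop = FALSE] +
        ff@mH * arr[, , 4L, drop = FALSE]) / waterMass(ff)
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
}

setMethod("show", "ForceField", function(object) {
  cat("Four-site water force field\n")
  cat(sprintf("  charges: qH = %+.4f e, qM = %+.4f e\n", object@qH, object@qM))
  cat(sprintf("  LJ (O-O): sigma = %.4f nm, epsilon = %.4f kJ/mol\n",
              object@sigmaOO, object@epsilonOO))
  cat(sprintf("  geometry: rOH = %.5f nm, HOH = %.2f deg, dOM = %.5f nm\n",
              object@rOH, object@thetaHOH, object@dOM))
  invisible(NULL)
})
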
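## Pairwise energy decomposition and the energetic interaction criterion.
##
## A pair (i, j) is energetically connected when
##   V_Coulomb + V_LJ + E_kin^ij + lambda * 4 * E_kin^H  <  0  (strictly),
## i.e. when the attraction between the molecules outweighs both their
## relative kinetic energy and a lambda-weighted thermal penalty for the
## four hydrogen atoms of the pair.

#' Hydrogen reference kinetic energy
#'
#' Kinetic energy per mole of a hydrogen-mass particle moving at the most
#' probable speed of the Maxwell-Boltzmann distribution at temperature T,
#' \eqn{v_p = \sqrt{2 k_B T / m_H}}.  Algebraically the mass cancels and
#' the value equals \eqn{R T}; it is computed through the velocity formula
#' to keep the physical definition explicit.
#'
#' @param temperature temperature (K), > 0
#' @param ff force field supplying the hydrogen mass
#' @return kinetic energy (kJ/mol)
#' @examples
#' hydrogenKineticEnergy(1.04 * 647.096)  # ~ 5.60 kJ/mol
#' @export
hydrogenKineticEnergy <- function(temperature, ff = tip4p2005()) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  vp <- sqrt(2 * .R_GAS * temperature / ff@mH)  # nm/ps
  0.5 * ff@mH * vp^2
}

#' Intermolecular Coulomb energy
#'
#' Sum of Coulomb's law over the 9 charged-site pairs (hydrogens and M site
#' of each molecule); plain Euclidean distances, no minimum image.
#'
#' @param molI,molJ molecules as returned by [molecule()] (lists with a
#'   3 x 4 \code{pos} matrix, sites H_a, O, M, H_b)
#' @param ff a [ForceField-class]
#' @return energy (kJ/mol)
#' @export
coulombEnergy <- function(molI, molJ, ff = tip4p2005()) {
  q <- c(ff@qH, ff@qM, ff@qH)          # Ha, M, Hb
  si <- molI$pos[, c(1L, 3L, 4L)]
  sj <- molJ$pos[, c(1L, 3L, 4L)]
  e <- 0
  for (a in 1:3) for (b in 1:3) {
    r <- sqrt(sum((si[, a] - sj[, b])^2))
    if (r == 0) stop("singularity: coincident charged sites")
    e <- e + ff@fCoulomb * q[a] * q[b] / r
  }
  e
}

#' Intermolecular Lennard-Jones energy
#'
#' Only the oxygen-oxygen interaction carries a Lennard-Jones term in the
#' four-site model: \eqn{4 \epsilon [(\sigma/r)^{12} - (\sigma/r)^6]}.
#'
#' @inheritParams coulombEnergy
#' @return energy (kJ/mol)
#' @export
lennardJonesEnergy <- function(molI, molJ, ff = tip4p2005()) {
  r <- sqrt(sum((molI$pos[, 2L] - molJ$pos[, 2L])^2))
  if (r == 0) stop("singularity: coincident oxygen sites")
  sr6 <- (ff@sigmaOO / r)^6
  4 * ff@epsilonOO * (sr6^2 - sr6)
}

#' Relative kinetic energy of a molecular pair
#'
#' Kinetic energy of the relative center-of-mass motion,
#' \eqn{\tfrac12 \mu |v_i - v_j|^2} with the two-body reduced mass
#' \eqn{\mu = m_w / 2} of two equal water molecules.  With masses in g/mol
#' and velocities in nm/ps the result is in kJ/mol with no conversion.
#'
#' @inheritParams coulombEnergy
#' @return kinetic energy (kJ/mol), >= 0
#' @export
pairKineticEnergy <- function(molI, molJ, ff = tip4p2005()) {
  mu <- waterMass(ff) / 2
  0.5 * mu * sum((molI$comVel - molJ$comVel)^2)
}

#' Construct criterion parameters
#'
#' @param lambda weight on the hydrogen thermal penalty (default the
#'   calibrated value 0.655)
#' @param temperature temperature (K) from which \code{EkinH} is derived
#'   when not given directly
#' @param EkinH hydrogen reference kinetic energy (kJ/mol); computed from
#'   \code{temperature} by default
#' @param rc interference cylinder radius (nm); default the oxygen diameter
#'   sigma_OO = 0.3159 nm
#' @param cubeFraction concentric-cube retention fraction (default 0.85)
#' @param pairCutoff COM-COM candidate pre-screen cutoff (nm, default 0.8)
#' @param ff force field used when deriving \code{EkinH}
#' @return a validated [CriterionParameters-class]
#' @examples
#' criterionParameters(lambda = 0.655, temperature = 1.04 * 647.096)
#' @export
criterionParameters <- function(lambda = 0.655, temperature = NULL,
                                EkinH = NULL, rc = 0.3159,
                                cubeFraction = 0.85, pairCutoff = 0.8,
                                ff = tip4p2005()) {
  if (is.null(EkinH)) {
    if (is.null(temperature))
      stop("supply either EkinH or temperature")
    EkinH <- hydrogenKineticEnergy(temperature, ff)
  }
  new("CriterionParameters", lambda = lambda, EkinH = EkinH, rc = rc,
      cubeFraction = cubeFraction, pairCutoff = pairCutoff)
}

#' Criterion total for a pair
#'
#' @param Vcoul,VLJ,EkinPair pair energies (kJ/mol)
#' @param params a [CriterionParameters-class]
#' @return V_coul + V_LJ + E_kin_pair + lambda * 4 * E_kin_H (kJ/mol)
#' @export
criterionTotal <- function(Vcoul, VLJ, EkinPair, params) {
  Vcoul + VLJ + EkinPair + params@lambda * 4 * params@EkinH
}

#' Does a pair pass the interaction criterion?
#'
#' @inheritParams criterionTotal
#' @return TRUE iff the criterion total is strictly negative
#' @export
passesCriterion <- function(Vcoul, VLJ, EkinPair, params) {
  criterionTotal(Vcoul, VLJ, EkinPair, params) < 0
}

#' Energy decomposition for all listed pairs of a frame
#'
#' Vectorized evaluation of the Coulomb, Lennard-Jones and relative kinetic
#' energies for an explicit list of molecule-id pairs.
#'
#' @param frame a [WaterFrame-class]
#' @param pairs 2-column matrix of molecule ids
#' @param ff a [ForceField-class]
#' @return data.frame with columns i, j, Vcoul, VLJ, Ekin
#' @export
pairEnergies <- function(frame, pairs, ff = tip4p2005()) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (!nrow(pairs))
    return(data.frame(i = integer(), j = integer(), Vcoul = numeric(),
                      VLJ = numeric(), Ekin = numeric()))
  ki <- match(pairs[, 1L], frame@ids)
  kj <- match(pairs[, 2L], frame@ids)
  if (anyNA(ki) || anyNA(kj)) stop("pair references unknown molecule id")

  q <- c(ff@qH, ff@qM, ff@qH)
  sites <- c(1L, 3L, 4L)  # Ha, M, Hb
  Vcoul <- numeric(nrow(pairs))
  for (a in 1:3) for (b in 1:3) {
    d2 <- (frame@pos[ki, 1L, sites[a]] - frame@pos[kj, 1L, sites[b]])^2 +
          (frame@pos[ki, 2L, sites[a]] - frame@pos[kj, 2L, sites[b]])^2 +
          (frame@pos[ki, 3L, sites[a]] - frame@pos[kj, 3L, sites[b]])^2
    if (any(d2 == 0)) stop("singularity: coincident charged sites")
    Vcoul <- Vcoul + ff@fCoulomb * q[a] * q[b] / sqrt(d2)
  }

  rOO2 <- (frame@pos[ki, 1L, 2L] - frame@pos[kj, 1L, 2L])^2 +
          (frame@pos[ki, 2L, 2L] - frame@pos[kj, 2L, 2L])^2 +
          (frame@pos[ki, 3L, 2L] - frame@pos[kj, 3L, 2L])^2
  if (any(rOO2 == 0)) stop("singularity: coincident oxygen sites")
  sr6 <- (ff@sigmaOO^2 / rOO2)^3
  VLJ <- 4 * ff@epsilonOO * (sr6^2 - sr6)

  cv <- .comPositions(frame@vel, ff)
  dv2 <- rowSums((cv[ki, , drop = FALSE] - cv[kj, , drop = FALSE])^2)
  Ekin <- 0.5 * (waterMass(ff) / 2) * dv2

  data.frame(i = pairs[, 1L], j = pairs[, 2L],
             Vcoul = Vcoul, VLJ = VLJ, Ekin = Ekin)
}
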
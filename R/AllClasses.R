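## S4 class definitions for the interaction-network pipeline.

.SITES <- c("Ha", "O", "M", "Hb")

#' Four-site water force-field parameters
#'
#' Holds the parameters of a rigid four-site water model: point charges on
#' the two hydrogens and the massless M site, a single Lennard-Jones center
#' on the oxygen, the rigid geometry (O-H length, H-O-H angle, O-M offset
#' along the bisector) and site masses.  The Coulomb prefactor
#' \eqn{f = 1/(4 \pi \epsilon_0)} is stored in kJ mol^-1 nm e^-2 so that all
#' energies come out in kJ/mol directly.
#'
#' @slot qH charge on each hydrogen site (e)
#' @slot qM charge on the M site (e); molecular neutrality requires
#'   \code{2 * qH + qM = 0}
#' @slot sigmaOO Lennard-Jones size parameter for the O-O interaction (nm)
#' @slot epsilonOO Lennard-Jones well depth for the O-O interaction (kJ/mol)
#' @slot mH,mO site masses (u = g/mol); M is massless
#' @slot rOH rigid O-H bond length (nm)
#' @slot thetaHOH rigid H-O-H angle (degrees)
#' @slot dOM O-M distance along the H-O-H bisector (nm)
#' @slot fCoulomb Coulomb prefactor (kJ mol^-1 nm e^-2)
#'
#' @seealso [tip4p2005()] for the default parameter set.
#' @export
setClass("ForceField",
  representation(
    qH = "numeric", qM = "numeric",
    sigmaOO = "numeric", epsilonOO = "numeric",
    mH = "numeric", mO = "numeric",
    rOH = "numeric", thetaHOH = "numeric", dOM = "numeric",
    fCoulomb = "numeric"
  )
)

setValidity("ForceField", function(object) {
  msgs <- character()
  if (abs(2 * object@qH + object@qM) > 1e-10)
    msgs <- c(msgs, "molecule must be neutral: 2*qH + qM = 0")
  if (object@sigmaOO <= 0) msgs <- c(msgs, "sigmaOO must be positive")
  if (object@epsilonOO <= 0) msgs <- c(msgs, "epsilonOO must be positive")
  if (object@mH <= 0 || object@mO <= 0) msgs <- c(msgs, "masses must be positive")
  if (object@rOH <= 0 || object@dOM < 0) msgs <- c(msgs, "invalid rigid geometry")
  if (length(msgs)) msgs else TRUE
})

#' Frame of four-site water molecules
#'
#' A single configuration: per-molecule positions and velocities of the four
#' sites H_a, O, M, H_b in an orthorhombic periodic box, plus optional
#' monatomic ions.  Positions are stored wrapped so that every molecular
#' center of mass lies in [0, L) per axis; molecules are wrapped rigidly
#' (whole-molecule lattice translation) so that intramolecular geometry is
#' never torn across the boundary.
#'
#' @slot box edge lengths of the orthorhombic box (nm), length 3
#' @slot pos numeric array \code{[n, 3, 4]}: molecule, axis (x/y/z), site
#'   (Ha, O, M, Hb), in nm
#' @slot vel numeric array with the same shape, in nm/ps
#' @slot ids integer molecule ids, unique
#' @slot ions data.frame with columns label, x, y, z, vx, vy, vz, charge
#' @slot temperature nominal temperature (K) or NA
#' @slot pressure nominal pressure (bar) or NA
#'
#' @seealso [waterFrame()], [readGro()], [generateWaterFrame()]
#' @export
setClass("WaterFrame",
  representation(
    box = "numeric",
    pos = "array",
    vel = "array",
    ids = "integer",
    ions = "data.frame",
    temperature = "numeric",
    pressure = "numeric"
  )
)

setValidity("WaterFrame", function(object) {
  msgs <- character()
  n <- length(object@ids)
  if (length(object@box) != 3L || any(object@box <= 0))
    msgs <- c(msgs, "box must be 3 positive edge lengths")
  if (!identical(dim(object@pos), c(n, 3L, 4L)))
    msgs <- c(msgs, "pos must be an [n, 3, 4] array")
  if (!identical(dim(object@vel), c(n, 3L, 4L)))
    msgs <- c(msgs, "vel must be an [n, 3, 4] array")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "molecule ids must be unique")
  if (n > 0L && identical(dim(object@pos), c(n, 3L, 4L))) {
    cm <- .comPositions(object@pos, tip4p2005())
    eps <- 1e-9
    for (ax in 1:3) {
      if (any(cm[, ax] < -eps | cm[, ax] >= object@box[ax] + eps)) {
        msgs <- c(msgs, "molecular centers of mass must lie inside the box")
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Parameters of the energetic interaction criterion
#'
#' Bundles the tunable quantities of the pair-interaction criterion: the
#' weight \code{lambda} on the hydrogen thermal-energy penalty, the
#' reference hydrogen kinetic energy \code{EkinH} (kJ/mol, normally
#' \eqn{k_B T} at the simulation temperature expressed per mole), the
#' interference-cylinder radius \code{rc} (nm), the concentric-cube
#' retention fraction, and the center-of-mass distance pre-screen cutoff
#' used when enumerating candidate pairs.
#'
#' @slot lambda dimensionless weight on the thermal penalty (>= 0)
#' @slot EkinH reference hydrogen kinetic energy (kJ/mol)
#' @slot rc interference cylinder radius (nm)
#' @slot cubeFraction edge fraction of the retained concentric cube, (0, 1]
#' @slot pairCutoff COM-COM candidate-pair cutoff (nm)
#'
#' @seealso [criterionParameters()]
#' @export
setClass("CriterionParameters",
  representation(
    lambda = "numeric", EkinH = "numeric", rc = "numeric",
    cubeFraction = "numeric", pairCutoff = "numeric"
  )
)

setValidity("CriterionParameters", function(object) {
  msgs <- character()
  if (object@lambda < 0) msgs <- c(msgs, "lambda must be >= 0")
  if (object@EkinH < 0) msgs <- c(msgs, "EkinH must be >= 0")
  if (object@rc < 0) msgs <- c(msgs, "rc must be >= 0")
  if (object@cubeFraction <= 0 || object@cubeFraction > 1)
    msgs <- c(msgs, "cubeFraction must be in (0, 1]")
  if (object@pairCutoff <= 0) msgs <- c(msgs, "pairCutoff must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Molecular interaction network
#'
#' Molecules as nodes, energetically significant pair interactions as
#' undirected edges.  \code{nodes} are the molecule ids that survived the
#' concentric-cube filter; \code{edges} carries the per-pair energy
#' decomposition (Coulomb, Lennard-Jones, relative kinetic energy, and the
#' criterion total including the lambda-weighted thermal penalty).
#'
#' @slot nodes integer molecule ids (cube-filtered node set)
#' @slot edges data.frame with columns i, j, Vcoul, VLJ, Ekin, total
#' @slot params the [CriterionParameters-class] in force when built
#'
#' @seealso [buildNetwork()], [asIgraph()], [interactingNodes()]
#' @export
setClass("InteractionNetwork",
  representation(
    nodes = "integer",
    edges = "data.frame",
    params = "CriterionParameters"
  )
)

setValidity("InteractionNetwork", function(object) {
  msgs <- character()
  e <- object@edges
  need <- c("i", "j", "Vcoul", "VLJ", "Ekin", "total")
  if (!all(need %in% names(e)))
    msgs <- c(msgs, "edges must have columns i, j, Vcoul, VLJ, Ekin, total")
  else if (nrow(e)) {
    if (!all(e$i %in% object@nodes) || !all(e$j %in% object@nodes))
      msgs <- c(msgs, "edge endpoints must be nodes")
    if (any(e$i == e$j)) msgs <- c(msgs, "self-loops are not allowed")
    key <- paste(pmin(e$i, e$j), pmax(e$i, e$j))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate undirected edges")
  }
  if (length(msgs)) msgs else TRUE
})

#' Distribution of connected-component sizes
#'
#' Counts n_c(s) of connected components of each size s (size-1 components
#' are monomers), with the totals needed for normalization.
#'
#' @slot sizes integer component sizes s with positive count
#' @slot counts integer n_c(s), parallel to \code{sizes}
#' @slot nComponents total number of components
#' @slot nNodes total number of nodes
#'
#' @seealso [componentSizeDistribution()], [fractions()], [fitPowerLaw()]
#' @export
setClass("ComponentSizeDistribution",
  representation(
    sizes = "integer", counts = "integer",
    nComponents = "integer", nNodes = "integer"
  )
)

setValidity("ComponentSizeDistribution", function(object) {
  msgs <- character()
  if (length(object@sizes) != length(object@counts))
    msgs <- c(msgs, "sizes and counts must be parallel")
  if (length(object@counts) && sum(object@counts) != object@nComponents)
    msgs <- c(msgs, "counts must sum to nComponents")
  if (length(object@counts) &&
      sum(as.numeric(object@sizes) * object@counts) != object@nNodes)
    msgs <- c(msgs, "sum of s * n_c(s) must equal nNodes")
  if (length(msgs)) msgs else TRUE
})

#' Power-law model of a component-size distribution
#'
#' Fit of n_c(s) = A * s^b by ordinary least squares on log n_c(s) versus
#' log s.  A is the model value at s = 1 (the monomer count under the
#' model); b < 0 is the decay exponent of component frequency with size.
#'
#' @slot A model intercept at s = 1 (> 0)
#' @slot b exponent
#' @slot rSquared coefficient of determination of the log-log regression
#'
#' @seealso [fitPowerLaw()]
#' @export
setClass("PowerLawFit",
  representation(A = "numeric", b = "numeric", rSquared = "numeric")
)

#' Result of a lambda calibration
#'
#' Errors of the pooled model component-size distribution against a
#' reference distribution over a grid of lambda values, and the minimizing
#' lambda (ties broken toward the smallest lambda).
#'
#' @slot grid lambda grid
#' @slot mae,rmse per-lambda mean absolute and root-mean-squared errors
#' @slot lambdaStar argmin-MAE lambda
#' @slot maeStar,rmseStar errors at lambdaStar
#'
#' @seealso [calibrateLambda()]
#' @export
setClass("CalibrationResult",
  representation(
    grid = "numeric", mae = "numeric", rmse = "numeric",
    lambdaStar = "numeric", maeStar = "numeric", rmseStar = "numeric"
  )
)

setValidity("CalibrationResult", function(object) {
  msgs <- character()
  if (length(object@grid) != length(object@mae) ||
      length(object@grid) != length(object@rmse))
    msgs <- c(msgs, "grid, mae and rmse must be parallel")
  if (!object@lambdaStar %in% object@grid)
    msgs <- c(msgs, "lambdaStar must belong to the grid")
  if (length(object@mae) && abs(object@maeStar - min(object@mae)) > 1e-12)
    msgs <- c(msgs, "maeStar must be the grid minimum")
  if (length(msgs)) msgs else TRUE
})
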
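## PCA-based representative selection: frames and connected components.

#' Flatten a frame to its coordinate vector
#'
#' One row per frame in the PCA layout: x, y, z of each of the 4 sites of
#' each molecule, i.e. 12 columns per molecule (8544 molecules give
#' 102,528 columns).
#'
#' @param frame a [WaterFrame-class]
#' @return numeric vector of length 12 * nMolecules
#' @export
flattenFrame <- function(frame) {
  ## molecule-major, then site, then axis
  as.numeric(aperm(frame@pos, c(2L, 3L, 1L)))
}

#' Select representative frames by PCA
#'
#' Flattens each frame to its coordinate vector, mean-centers across
#' frames (no per-column scaling: all columns share units), projects onto
#' the leading principal components (the smallest number explaining at
#' least \code{varianceTarget} of the variance, minimum 2), and returns
#' the indices of the \code{n} frames whose projections are closest to
#' the origin, i.e. to the mean of the distribution.  Ties go to the
#' lower frame index.
#'
#' @param frames list of [WaterFrame-class] objects with identical
#'   molecule counts and site order
#' @param n number of frames to select (default 3)
#' @param varianceTarget retained-variance threshold (default 0.90)
#' @return integer frame indices, closest first
#' @export
selectRepresentativeFrames <- function(frames, n = 3L, varianceTarget = 0.90) {
  stopifnot(length(frames) >= 1L)
  if (n > length(frames)) {
    warning("n exceeds the number of frames; returning all")
    n <- length(frames)
  }
  X <- do.call(rbind, lapply(frames, flattenFrame))
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = min(dim(Xc)), nv = 0L)
  ev <- sv$d^2
  total <- sum(ev)
  if (total < .Machine$double.eps * nrow(X)) {
    ## degenerate cloud: all frames identical; all distances are zero
    return(seq_len(n))
  }
  k <- which(cumsum(ev) / total >= varianceTarget)[1L]
  k <- min(max(k, 2L), length(ev))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      nrow = k)
  d <- sqrt(rowSums(scores^2))
  order(d, seq_along(d))[seq_len(n)]
}

#' Descriptors of multi-molecule components
#'
#' Four per-component statistics used for representative selection:
#' the sum and population standard deviation of the component's bond
#' lengths (O-O distances of its edges, nm) and the mean and population
#' standard deviation of its edge interaction energies (the pair potential
#' V_coul + V_LJ, kJ/mol; kinetic terms describe instantaneous motion, not
#' the bond, and are excluded).
#'
#' @param net an [InteractionNetwork-class]
#' @param frame the frame the network was built from
#' @param ff a [ForceField-class]
#' @return data.frame with columns id (smallest member id), size,
#'   topology, sumLength, sdLength, meanEnergy, sdEnergy; one row per
#'   component of size >= 2 (zero rows if none)
#' @export
componentDescriptors <- function(net, frame, ff = tip4p2005()) {
  comps <- connectedComponents(net)
  comps <- comps[vapply(comps, length, integer(1L)) >= 2L]
  out <- data.frame(id = integer(), size = integer(), topology = character(),
                    sumLength = numeric(), sdLength = numeric(),
                    meanEnergy = numeric(), sdEnergy = numeric())
  if (!length(comps)) return(out)
  e <- net@edges
  ki <- match(e$i, frame@ids)
  kj <- match(e$j, frame@ids)
  oo <- sqrt((frame@pos[ki, 1L, 2L] - frame@pos[kj, 1L, 2L])^2 +
             (frame@pos[ki, 2L, 2L] - frame@pos[kj, 2L, 2L])^2 +
             (frame@pos[ki, 3L, 2L] - frame@pos[kj, 3L, 2L])^2)
  pot <- e$Vcoul + e$VLJ
  popSd <- function(x) if (length(x) > 1L) sqrt(mean((x - mean(x))^2)) else 0
  rows <- lapply(comps, function(m) {
    sel <- e$i %in% m & e$j %in% m
    data.frame(id = min(m), size = length(m),
               topology = classifyComponentTopology(m, e),
               sumLength = sum(oo[sel]), sdLength = popSd(oo[sel]),
               meanEnergy = mean(pot[sel]), sdEnergy = popSd(pot[sel]))
  })
  do.call(rbind, rows)
}

#' Select the representative component of a group
#'
#' Within one size/topology group, z-scores the four descriptor columns,
#' projects by PCA, and returns the id of the component closest to the
#' origin (the group mean) in the projected space.  All components are
#' retained (PCA is an isometry on the full retained space).  Ties go to
#' the lowest id.
#'
#' @param descriptors data.frame as from [componentDescriptors()],
#'   already restricted to the group of interest
#' @return the representative component id
#' @export
selectRepresentativeComponent <- function(descriptors) {
  if (!nrow(descriptors)) stop("empty descriptor group")
  if (nrow(descriptors) == 1L) return(descriptors$id[1L])
  M <- as.matrix(descriptors[, c("sumLength", "sdLength",
                                 "meanEnergy", "sdEnergy")])
  Z <- apply(M, 2L, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  p <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  d <- sqrt(rowSums(p$x^2))
  descriptors$id[order(d, descriptors$id)][1L]
}
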
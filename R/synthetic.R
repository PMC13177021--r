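## Synthetic configuration generator: thermally agitated rigid four-site
## water, frames with planted clusters of known sizes, and synthetic BCP
## tables with ground-truth labels.  Not a physics simulator: no forces,
## no integration, no thermostats.

## Local-frame site geometry (3 x 4, sites Ha, O, M, Hb): O at the origin,
## H-O-H bisector along +z, hydrogens in the xz plane.
.rigidSites <- function(ff) {
  th <- ff@thetaHOH * pi / 180
  s <- sin(th / 2); cz <- cos(th / 2)
  cbind(Ha = ff@rOH * c(s, 0, cz),
        O  = c(0, 0, 0),
        M  = ff@dOM * c(0, 0, 1),
        Hb = ff@rOH * c(-s, 0, cz))
}

## Uniform random rotation matrices via unit quaternions.
.randomRotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

## Per-axis Maxwell-Boltzmann COM velocity sd for mass m (g/mol) at T (K),
## in nm/ps:  var = R T / m.
.mbSd <- function(temperature, mass) sqrt(.R_GAS * temperature / mass)

#' Generate a thermally agitated water frame
#'
#' Oxygen positions by rejection sampling with a pairwise O-O minimum
#' separation, uniformly random rigid orientations, H/M sites from the
#' rigid model geometry, and center-of-mass velocities drawn per axis
#' from the Maxwell-Boltzmann distribution at the requested temperature
#' (rigid-body translation only; all four sites share the molecule's COM
#' velocity).  Reproducible for a fixed seed.
#'
#' @param n number of molecules
#' @param box box edge (nm; scalar or length 3)
#' @param temperature temperature (K) for the velocity distribution
#' @param seed integer seed, or NULL to use the current RNG state
#' @param minSep minimum O-O separation (nm, default 0.25)
#' @param ff a [ForceField-class]
#' @param maxAttempts rejection-sampling attempts per molecule
#' @return a [WaterFrame-class]
#' @export
generateWaterFrame <- function(n, box, temperature = 673, seed = NULL,
                               minSep = 0.25, ff = tip4p2005(),
                               maxAttempts = 500L) {
  if (!is.null(seed)) set.seed(seed)
  box <- rep_len(as.numeric(box), 3L)
  pos <- array(0, c(n, 3L, 4L))
  vel <- array(0, c(n, 3L, 4L))
  if (n > 0L) {
    ## cell list over O positions for the min-separation test
    cell <- pmax(minSep, 1e-6)
    dims <- pmax(1L, as.integer(floor(box / cell)))
    cellOf <- function(p) pmin(dims - 1L, as.integer(floor(p / (box / dims))))
    occ <- new.env(hash = TRUE, parent = emptyenv())
    O <- matrix(0, n, 3L)
    for (k in seq_len(n)) {
      placed <- FALSE
      for (a in seq_len(maxAttempts)) {
        p <- stats::runif(3L) * box
        cc <- cellOf(p)
        ok <- TRUE
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          key <- paste((cc[1] + dx) %% dims[1], (cc[2] + dy) %% dims[2],
                       (cc[3] + dz) %% dims[3])
          others <- occ[[key]]
          if (!is.null(others)) {
            d2 <- rowSums((O[others, , drop = FALSE] -
                           matrix(p, length(others), 3L, byrow = TRUE))^2)
            if (any(d2 < minSep^2)) { ok <- FALSE; break }
          }
        }
        if (ok) {
          O[k, ] <- p
          key <- paste(cc[1], cc[2], cc[3])
          occ[[key]] <- c(occ[[key]], k)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("packing failure: could not place molecule ", k,
             " with minSep = ", minSep, " in the given box")
    }
    local <- .rigidSites(ff)
    sdv <- .mbSd(temperature, waterMass(ff))
    for (k in seq_len(n)) {
      rot <- .randomRotation()
      pos[k, , ] <- rot %*% local + O[k, ]
      vel[k, , ] <- matrix(stats::rnorm(3L, sd = sdv), 3L, 4L)
    }
  }
  waterFrame(pos, vel, box = box, temperature = temperature, ff = ff)
}

#' Frame with planted clusters of known sizes
#'
#' Builds isolated linear chains (hydrogen-bond-like motif: each donor
#' O-H points at the next oxygen along the chain axis, O-O at the given
#' spacing) on a coarse grid so that distinct clusters are separated by
#' more than the candidate-pair cutoff, entirely inside the concentric
#' retention cube.  Members of one cluster share a single COM velocity
#' drawn at \code{tCold} (zero relative motion), so every planted edge
#' passes the energetic criterion while no spurious inter-cluster edge
#' can form.  Ground-truth component membership is returned alongside.
#'
#' @param spec named vector: component size -> count, e.g.
#'   \code{c(`1` = 10, `2` = 5, `3` = 2)}
#' @param spacing intra-chain O-O distance (nm, default 0.28); either a
#'   scalar or one value per cluster (recycled), which makes graded pair
#'   energies across clusters possible

#' @param tCold temperature (K) of the per-cluster COM velocities
#'   (default 30 K: thermal noise small against the pair attraction)
#' @param seed integer seed or NULL
#' @param pairCutoff the candidate cutoff clusters must exceed (nm)
#' @param cubeFraction retention-cube fraction the layout must respect
#' @param ff a [ForceField-class]
#' @return list with elements \code{frame} (a [WaterFrame-class]) and
#'   \code{labels} (integer cluster id per molecule, named by molecule id)
#' @export
plantedClusterFrame <- function(spec, spacing = 0.28, tCold = 30,
                                seed = NULL, pairCutoff = 0.8,
                                cubeFraction = 0.85, ff = tip4p2005()) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- as.integer(names(spec))
  counts <- as.integer(spec)
  stopifnot(all(sizes >= 1L), all(counts >= 0L), all(spacing > 0))
  clusterSizes <- rep(sizes, counts)
  nClusters <- length(clusterSizes)
  spacing <- rep_len(spacing, max(nClusters, 1L))
  n <- sum(clusterSizes)
  if (n == 0L) {
    fr <- waterFrame(array(0, c(0L, 3L, 4L)), box = 3, ff = ff)
    return(list(frame = fr, labels = stats::setNames(integer(), character())))
  }

  ## chain motif: donor H_a along +x toward the next oxygen; successive
  ## molecules are flipped about the chain axis (the twist that minimizes
  ## the pair potential, ~ -21.4 kJ/mol at 0.28 nm), so every planted
  ## edge clears the criterion with a wide margin
  th <- ff@thetaHOH * pi / 180
  u1 <- c(1, 0, 0)
  u2 <- c(cos(th), sin(th), 0)
  bis <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
  local <- cbind(Ha = ff@rOH * u1, O = c(0, 0, 0),
                 M = ff@dOM * bis, Hb = ff@rOH * u2)
  flip <- diag(c(1, -1, -1))  # 180 degree rotation about the chain axis
  localFlip <- flip %*% local

  chainLen <- (max(clusterSizes) - 1L) * max(spacing)
  gap <- pairCutoff + 0.2
  cell <- chainLen + gap
  m <- ceiling(nClusters^(1 / 3))
  region <- m * cell
  box <- region / min(cubeFraction, 0.8)  # keep everything inside the cube
  offset <- (box - region) / 2

  pos <- array(0, c(n, 3L, 4L))
  vel <- array(0, c(n, 3L, 4L))
  labels <- integer(n)
  mol <- 0L
  sdv <- .mbSd(tCold, waterMass(ff))
  for (c_ in seq_len(nClusters)) {
    ci <- c_ - 1L
    cellIdx <- c(ci %% m, (ci %/% m) %% m, ci %/% (m * m))
    origin <- offset + cellIdx * cell + gap / 4
    for (k in seq_len(clusterSizes[c_])) {
      mol <- mol + 1L
      O <- origin + c((k - 1L) * spacing[c_], 0, 0)
      pos[mol, , ] <- (if (k %% 2L) local else localFlip) + O
      vel[mol, , ] <- matrix(stats::rnorm(3L, sd = sdv), 3L, 4L)
      labels[mol] <- c_
    }
  }
  fr <- waterFrame(pos, vel, box = box, temperature = tCold, ff = ff)
  list(frame = fr, labels = stats::setNames(labels, fr@ids))
}

#' Synthetic BCP table with ground-truth classes
#'
#' Samples bond-critical-point records strictly inside each class's
#' defining region (noncovalent: Laplacian > 0, H > 0; partially
#' covalent: Laplacian > 0, H < 0; covalent: Laplacian < 0, H < 0), with
#' G >= 0, V < 0 and the identity V = -G - K holding exactly.
#'
#' @param n number of records
#' @param mix named fractions summing to 1 over the classes
#'   noncovalent, partially_covalent, covalent
#' @param seed integer seed or NULL
#' @return BCP data.frame (see [bcpTable()]) with an extra
#'   \code{trueLabel} column
#' @export
syntheticBcpTable <- function(n,
                              mix = c(noncovalent = 0.85,
                                      partially_covalent = 0.15,
                                      covalent = 0),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(mix) - 1) < 1e-9)
  classes <- c("noncovalent", "partially_covalent", "covalent")
  mix <- mix[classes]
  mix[is.na(mix)] <- 0
  counts <- floor(n * mix)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(n * mix - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1L
  }
  rows <- list()
  if (counts[1L] > 0) {  # noncovalent: lap > 0, H > 0 (so 0 < H < G)
    G <- stats::runif(counts[1L], 0.008, 0.02)
    H <- stats::runif(counts[1L], 0.1, 0.5) * G
    rows[[1L]] <- data.frame(rho = stats::runif(counts[1L], 0.005, 0.03),
                             laplacian = stats::runif(counts[1L], 0.02, 0.12),
                             G = G, V = H - G,
                             trueLabel = "noncovalent")
  }
  if (counts[2L] > 0) {  # partially covalent: lap > 0, H < 0, |H| < G
    G <- stats::runif(counts[2L], 0.02, 0.05)
    H <- -stats::runif(counts[2L], 0.1, 0.5) * G
    rows[[2L]] <- data.frame(rho = stats::runif(counts[2L], 0.02, 0.06),
                             laplacian = stats::runif(counts[2L], 0.02, 0.12),
                             G = G, V = H - G,
                             trueLabel = "partially_covalent")
  }
  if (counts[3L] > 0) {  # covalent: lap < 0, H < 0
    G <- stats::runif(counts[3L], 0.05, 0.3)
    H <- -stats::runif(counts[3L], 0.05, 0.3)
    rows[[3L]] <- data.frame(rho = stats::runif(counts[3L], 0.2, 0.4),
                             laplacian = -stats::runif(counts[3L], 0.1, 1.0),
                             G = G, V = H - G,
                             trueLabel = "covalent")
  }
  if (!length(rows))
    return(bcpTable(data.frame(rho = numeric(), laplacian = numeric(),
                               G = numeric(), V = numeric()))[0, ])
  df <- do.call(rbind, rows)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  bcpTable(df)
}
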
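## Independent brute-force oracles, implemented separately from the
## package internals: explicit loops, dense matrices, no shared code
## paths with the functions they check.

## Coulomb: explicit double loop over the charged sites of both molecules.
bfCoulomb <- function(molI, molJ, ff = tip4p2005()) {
  siteCharge <- c(Ha = ff@qH, O = 0, M = ff@qM, Hb = ff@qH)
  sites <- c("Ha", "O", "M", "Hb")
  e <- 0
  for (a in 1:4) for (b in 1:4) {
    qa <- siteCharge[[sites[a]]]
    qb <- siteCharge[[sites[b]]]
    if (qa == 0 || qb == 0) next
    r <- sqrt(sum((molI$pos[, a] - molJ$pos[, b])^2))
    e <- e + ff@fCoulomb * qa * qb / r
  }
  e
}

## Lennard-Jones from first principles on the O sites.
bfLJ <- function(molI, molJ, ff = tip4p2005()) {
  r <- sqrt(sum((molI$pos[, 2] - molJ$pos[, 2])^2))
  4 * ff@epsilonOO * ((ff@sigmaOO / r)^12 - (ff@sigmaOO / r)^6)
}

## Connected components by explicit depth-first labeling.
dfsComponents <- function(nodes, edges) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)),
                                as.character(nodes)), identity)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    i <- as.character(edges$i[r]); j <- as.character(edges$j[r])
    adj[[i]] <- c(adj[[i]], edges$j[r])
    adj[[j]] <- c(adj[[j]], edges$i[r])
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), as.character(nodes))
  comps <- list()
  for (v in nodes) {
    if (seen[[as.character(v)]]) next
    stack <- v
    members <- integer()
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      uk <- as.character(u)
      if (seen[[uk]]) next
      seen[[uk]] <- TRUE
      members <- c(members, u)
      stack <- c(stack, adj[[uk]])
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

## PageRank by dense power iteration on the explicit transition matrix.
## Dangling nodes redistribute uniformly; uniform teleportation.
powerIterationPageRank <- function(nodes, edges, damping = 0.85,
                                   tol = 1e-12, maxIter = 100000) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    i <- as.character(edges$i[r]); j <- as.character(edges$j[r])
    A[i, j] <- A[i, j] + 1
    A[j, i] <- A[j, i] + 1
  }
  deg <- rowSums(A)
  P <- matrix(1 / n, n, n)
  nz <- deg > 0
  P[nz, ] <- A[nz, , drop = FALSE] / deg[nz]
  v <- rep(1 / n, n)
  for (it in seq_len(maxIter)) {
    vNew <- damping * as.numeric(v %*% P) + (1 - damping) / n
    if (sum(abs(vNew - v)) < tol) break
    v <- vNew
  }
  stats::setNames(vNew, nodes)
}

## All-pairs candidate enumeration by explicit double loop on COMs.
allPairsCandidates <- function(frame, ids, cutoff, ff = tip4p2005()) {
  cm <- com(frame, ff)
  k <- match(ids, frame@ids)
  out <- NULL
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a >= b) next
    if (sqrt(sum((cm[k[a], ] - cm[k[b], ])^2)) <= cutoff)
      out <- rbind(out, c(min(ids[a], ids[b]), max(ids[a], ids[b])))
  }
  if (is.null(out)) return(matrix(integer(), ncol = 2))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

## A hand-placed hydrogen-bonded dimer with a fixed geometry known to
## pass the criterion at the calibrated lambda and supercritical T.
boundDimerFrame <- function(dOO = 0.28, box = 4, vel2 = c(0, 0, 0)) {
  ff <- tip4p2005()
  th <- ff@thetaHOH * pi / 180
  u1 <- c(1, 0, 0); u2 <- c(cos(th), sin(th), 0)
  bis <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
  loc <- cbind(ff@rOH * u1, c(0, 0, 0), ff@dOM * bis, ff@rOH * u2)
  flip <- diag(c(1, -1, -1))
  pos <- array(0, c(2, 3, 4))
  center <- c(box / 2, box / 2, box / 2)
  pos[1, , ] <- loc + center
  pos[2, , ] <- flip %*% loc + center + c(dOO, 0, 0)
  vel <- array(0, c(2, 3, 4))
  vel[2, , ] <- matrix(vel2, 3, 4)
  waterFrame(pos, vel, box = box)
}

## Rigid four-site geometry built independently of the package internals:
## O at the origin, bisector along +z, hydrogens in the xz plane.
.rigidSitesForTest <- function(ff = tip4p2005()) {
  half <- ff@thetaHOH * pi / 360
  cbind(ff@rOH * c(sin(half), 0, cos(half)),
        c(0, 0, 0),
        ff@dOM * c(0, 0, 1),
        ff@rOH * c(-sin(half), 0, cos(half)))
}

## Random sprinkling of molecules, convenience wrapper with loose packing.
randomTestFrame <- function(n, box = 3, temperature = 673, seed = 1) {
  generateWaterFrame(n, box = box, temperature = temperature, seed = seed,
                     minSep = 0.24)
}
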
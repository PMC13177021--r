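## Geometric filters and assembly of the interaction network.

#' Molecules inside the concentric cube
#'
#' Ids of molecules whose center of mass lies inside the concentric
#' axis-aligned box with edges \code{cubeFraction * L} per axis.  The
#' filter removes molecules near the periodic boundary, whose pair
#' distances would otherwise be computed across the box without minimum
#' image.
#'
#' @param frame a [WaterFrame-class]
#' @param cubeFraction retained edge fraction, (0, 1]
#' @param ff force field for the centers of mass
#' @return integer vector of molecule ids
#' @export
innerCubeIds <- function(frame, cubeFraction = 0.85, ff = tip4p2005()) {
  stopifnot(cubeFraction > 0, cubeFraction <= 1)
  if (nMolecules(frame) == 0L) return(integer())
  cm <- com(frame, ff)
  keep <- rep(TRUE, nrow(cm))
  for (ax in 1:3) {
    lo <- frame@box[ax] * (1 - cubeFraction) / 2
    hi <- frame@box[ax] - lo
    keep <- keep & cm[, ax] >= lo & cm[, ax] <= hi
  }
  frame@ids[keep]
}

#' Third-body interference test
#'
#' TRUE when at least one third-body point lies inside the finite cylinder
#' of radius \code{rc} whose axis is the segment between \code{comI} and
#' \code{comJ}: the axial projection must fall strictly between the
#' endpoints and the radial distance must be at most \code{rc}.
#'
#' @param comI,comJ centers of mass of the candidate pair (length-3)
#' @param third matrix of third-body points (rows) or a length-3 vector
#' @param rc cylinder radius (nm)
#' @return logical
#' @export
cylinderBlocked <- function(comI, comJ, third, rc) {
  axis <- comJ - comI
  len2 <- sum(axis^2)
  if (len2 == 0) stop("degenerate axis: coincident centers of mass")
  if (is.null(dim(third))) third <- matrix(third, ncol = 3L)
  if (!nrow(third)) return(FALSE)
  rel <- sweep(third, 2L, comI)
  t <- as.numeric(rel %*% axis) / len2
  inside <- t > 0 & t < 1
  if (!any(inside)) return(FALSE)
  perp2 <- rowSums(rel[inside, , drop = FALSE]^2) - t[inside]^2 * len2
  any(perp2 <= rc^2 + 1e-15)
}

#' Candidate pairs within a COM-COM cutoff
#'
#' All unordered pairs of the given molecule ids whose center-of-mass
#' distance does not exceed \code{cutoff}, found with a cell list (linked
#' to a dense all-pairs scan for small sets).  With a large enough cutoff
#' this is a conservative superset of every criterion-passing pair.
#'
#' @param frame a [WaterFrame-class]
#' @param ids molecule ids to consider (default: all)
#' @param cutoff COM-COM distance cutoff (nm)
#' @param ff force field for the centers of mass
#' @return 2-column integer matrix of id pairs with i < j in id order
#' @export
candidatePairs <- function(frame, ids = frame@ids, cutoff = 0.8,
                           ff = tip4p2005()) {
  stopifnot(cutoff > 0)
  k <- match(ids, frame@ids)
  if (anyNA(k)) stop("unknown molecule ids")
  n <- length(k)
  if (n < 2L) return(matrix(integer(), ncol = 2L))
  cm <- com(frame, ff)[k, , drop = FALSE]

  if (n <= 400L) {
    d <- as.matrix(stats::dist(cm))
    hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    pr <- cbind(ids[hit[, 1L]], ids[hit[, 2L]])
  } else {
    cell <- floor(sweep(cm, 2L, c(0, 0, 0)) / cutoff)
    key <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
    byCell <- split(seq_len(n), key)
    cellCoords <- lapply(strsplit(names(byCell), " "), as.numeric)
    lookup <- new.env(hash = TRUE, parent = emptyenv())
    for (ci in seq_along(byCell)) assign(names(byCell)[ci], ci, envir = lookup)
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    out <- vector("list", length(byCell))
    for (ci in seq_along(byCell)) {
      me <- byCell[[ci]]
      cc <- cellCoords[[ci]]
      neigh <- integer()
      for (r in seq_len(nrow(off))) {
        nk <- paste(cc[1] + off[r, 1], cc[2] + off[r, 2], cc[3] + off[r, 3])
        cj <- lookup[[nk]]
        if (!is.null(cj) && cj >= ci)
          neigh <- c(neigh, if (cj == ci) integer() else byCell[[cj]])
      }
      cand1 <- if (length(me) > 1L) t(utils::combn(me, 2L)) else
        matrix(integer(), ncol = 2L)
      cand2 <- if (length(neigh)) cbind(rep(me, each = length(neigh)),
                                        rep(neigh, length(me))) else
        matrix(integer(), ncol = 2L)
      cand <- rbind(cand1, cand2)
      if (nrow(cand)) {
        d2 <- rowSums((cm[cand[, 1L], , drop = FALSE] -
                       cm[cand[, 2L], , drop = FALSE])^2)
        cand <- cand[d2 <= cutoff^2, , drop = FALSE]
      }
      out[[ci]] <- cand
    }
    pr <- do.call(rbind, out)
    if (nrow(pr)) {
      pr <- cbind(ids[pr[, 1L]], ids[pr[, 2L]])
    } else pr <- matrix(integer(), ncol = 2L)
  }
  if (nrow(pr)) {
    pr <- cbind(pmin(pr[, 1L], pr[, 2L]), pmax(pr[, 1L], pr[, 2L]))
    pr <- unique(pr)
    pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
  }
  storage.mode(pr) <- "integer"
  colnames(pr) <- c("i", "j")
  pr
}

#' Build the interaction network of a frame
#'
#' Applies the full pipeline: concentric-cube node filter, candidate-pair
#' pre-screen, third-body interference cylinder (all other molecules and,
#' optionally, ions act as blockers), and the energetic criterion.
#'
#' @param frame a [WaterFrame-class]
#' @param params a [CriterionParameters-class]
#' @param ff a [ForceField-class]
#' @param ionsBlock should ions count as interfering third bodies?
#' @return an [InteractionNetwork-class]
#' @examples
#' fr <- generateWaterFrame(50, box = 2.5, temperature = 673, seed = 1)
#' net <- buildNetwork(fr, criterionParameters(temperature = 673))
#' @export
buildNetwork <- function(frame, params, ff = tip4p2005(), ionsBlock = TRUE) {
  nodes <- innerCubeIds(frame, params@cubeFraction, ff)
  emptyEdges <- data.frame(i = integer(), j = integer(), Vcoul = numeric(),
                           VLJ = numeric(), Ekin = numeric(),
                           total = numeric())
  if (length(nodes) < 2L)
    return(new("InteractionNetwork", nodes = nodes, edges = emptyEdges,
               params = params))

  pairs <- candidatePairs(frame, nodes, params@pairCutoff, ff)
  if (!nrow(pairs))
    return(new("InteractionNetwork", nodes = nodes, edges = emptyEdges,
               params = params))

  ## third bodies: every molecule COM in the full frame, plus ion positions
  cm <- com(frame, ff)
  blockers <- cm
  if (ionsBlock && nrow(frame@ions))
    blockers <- rbind(blockers, as.matrix(frame@ions[, c("x", "y", "z")]))
  idxI <- match(pairs[, 1L], frame@ids)
  idxJ <- match(pairs[, 2L], frame@ids)
  nmol <- nrow(cm)
  open <- logical(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    keep <- rep(TRUE, nrow(blockers))
    keep[c(idxI[p], idxJ[p])] <- FALSE
    open[p] <- !cylinderBlocked(cm[idxI[p], ], cm[idxJ[p], ],
                                blockers[keep, , drop = FALSE], params@rc)
  }
  pairs <- pairs[open, , drop = FALSE]
  if (!nrow(pairs))
    return(new("InteractionNetwork", nodes = nodes, edges = emptyEdges,
               params = params))

  en <- pairEnergies(frame, pairs, ff)
  en$total <- criterionTotal(en$Vcoul, en$VLJ, en$Ekin, params)
  en <- en[en$total < 0, , drop = FALSE]
  rownames(en) <- NULL
  new("InteractionNetwork", nodes = nodes, edges = en, params = params)
}

#' @rdname interactingNodes
#' @export
setMethod("interactingNodes", "InteractionNetwork", function(x) {
  sort(unique(c(x@edges$i, x@edges$j)))
})

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "InteractionNetwork", function(x) {
  g <- igraph::make_empty_graph(n = length(x@nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(x@nodes))
  if (nrow(x@edges))
    g <- igraph::add_edges(g, rbind(as.character(x@edges$i),
                                    as.character(x@edges$j)))
  g
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges (%d interacting)\n",
              length(object@nodes), nrow(object@edges),
              length(interactingNodes(object))))
  cat(sprintf("  lambda = %.3f, EkinH = %.4f kJ/mol, rc = %.4f nm\n",
              object@params@lambda, object@params@EkinH, object@params@rc))
  invisible(NULL)
})

#' Write the edge table as TSV
#'
#' Columns i, j, V_coul, V_LJ, E_kin_pair, criterion_total at 6 decimals.
#'
#' @param net an [InteractionNetwork-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeEdgeTable <- function(net, path) {
  e <- net@edges
  out <- data.frame(i = e$i, j = e$j,
                    V_coul = sprintf("%.6f", e$Vcoul),
                    V_LJ = sprintf("%.6f", e$VLJ),
                    E_kin_pair = sprintf("%.6f", e$Ekin),
                    criterion_total = sprintf("%.6f", e$total))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
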
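## Network metrics, connected components, and component topology labels.

#' Network density
#'
#' \eqn{\rho = 2E / (N (N - 1))}: the fraction of realized edges out of all
#' possible ones.  With \code{mode = "all"} N counts every cube-filtered
#' node; with \code{mode = "interacting"} only nodes of degree >= 1 (the
#' shrinking denominator is why the two variants can trend in opposite
#' directions as monomers appear).
#'
#' @param net an [InteractionNetwork-class]
#' @param mode "all" or "interacting"
#' @return density in [0, 1]
#' @export
networkDensity <- function(net, mode = c("all", "interacting")) {
  mode <- match.arg(mode)
  N <- if (mode == "all") length(net@nodes) else length(interactingNodes(net))
  if (N < 2L) stop("density undefined for fewer than 2 nodes")
  2 * nrow(net@edges) / (N * (N - 1))
}

#' Average degree
#'
#' \eqn{\langle k \rangle = 2E / N} over the all-nodes set; identical to
#' the arithmetic mean of the individual node degrees.
#'
#' @param net an [InteractionNetwork-class]
#' @return mean degree
#' @export
averageDegree <- function(net) {
  N <- length(net@nodes)
  if (N < 1L) stop("average degree undefined for an empty node set")
  2 * nrow(net@edges) / N
}

#' PageRank of the interaction network
#'
#' Stationary distribution of the damped random walk on the undirected
#' graph (each edge walked both ways); degree-0 nodes redistribute their
#' probability uniformly.  Computed with igraph's PRPACK backend.
#'
#' @param net an [InteractionNetwork-class]
#' @param damping damping factor in (0, 1), default 0.85
#' @return named numeric vector (node id -> probability), summing to 1
#' @export
pageRank <- function(net, damping = 0.85) {
  stopifnot(damping > 0, damping < 1)
  if (!length(net@nodes)) stop("PageRank undefined for an empty node set")
  pr <- igraph::page_rank(asIgraph(net), damping = damping)$vector
  pr
}

#' Mean PageRank over interacting nodes
#'
#' Average visiting probability over degree >= 1 nodes (monomers excluded);
#' the all-node mean is trivially 1/N and is returned alongside.
#'
#' @inheritParams pageRank
#' @return list with elements \code{interacting} and \code{all}
#' @export
pageRankMean <- function(net, damping = 0.85) {
  pr <- pageRank(net, damping)
  act <- as.character(interactingNodes(net))
  list(interacting = if (length(act)) mean(pr[act]) else NA_real_,
       all = mean(pr))
}

#' Connected components
#'
#' @param net an [InteractionNetwork-class]
#' @return list of integer vectors of molecule ids, one per maximal
#'   connected component (isolated nodes are size-1 components), ordered
#'   by smallest member id
#' @export
connectedComponents <- function(net) {
  if (!length(net@nodes)) return(list())
  comp <- igraph::components(asIgraph(net))
  ids <- as.integer(names(comp$membership))
  out <- split(ids, comp$membership)
  out <- lapply(out, sort)
  names(out) <- NULL
  out[order(vapply(out, min, integer(1L)))]
}

#' Component-size distribution
#'
#' Counts n_c(s) of connected components of each size s, monomers
#' included.
#'
#' @param net an [InteractionNetwork-class]
#' @return a [ComponentSizeDistribution-class]
#' @export
componentSizeDistribution <- function(net) {
  comps <- connectedComponents(net)
  sizes <- vapply(comps, length, integer(1L))
  componentSizeCounts(table(sizes))
}

#' Component-size distribution from explicit counts
#'
#' @param counts named vector or table: size -> count
#' @return a [ComponentSizeDistribution-class]
#' @export
componentSizeCounts <- function(counts) {
  s <- as.integer(names(counts))
  n <- as.integer(counts)
  keep <- n > 0L
  s <- s[keep]; n <- n[keep]
  o <- order(s)
  new("ComponentSizeDistribution", sizes = s[o], counts = n[o],
      nComponents = sum(n), nNodes = as.integer(sum(s * as.numeric(n))))
}

#' @rdname fractions
#' @export
setMethod("fractions", "ComponentSizeDistribution", function(x) {
  if (x@nComponents == 0L) return(stats::setNames(numeric(), character()))
  stats::setNames(x@counts / x@nComponents, x@sizes)
})

setMethod("show", "ComponentSizeDistribution", function(object) {
  cat(sprintf("ComponentSizeDistribution: %d components over %d nodes\n",
              object@nComponents, object@nNodes))
  if (length(object@sizes)) {
    df <- data.frame(size = object@sizes, count = object@counts,
                     fraction = round(object@counts / object@nComponents, 4))
    print(df, row.names = FALSE)
  }
  invisible(NULL)
})

#' Classify the topology of a component
#'
#' A size >= 2 component is \code{linear} when it is a simple path (every
#' degree <= 2 and edge count = size - 1), \code{cyclic} when it has at
#' least as many edges as nodes, and \code{branched} otherwise.
#'
#' @param memberIds integer ids of the component's nodes
#' @param edges edge data.frame (columns i, j), e.g. \code{net@edges}
#' @return "linear", "branched" or "cyclic"
#' @export
classifyComponentTopology <- function(memberIds, edges) {
  if (length(memberIds) < 2L)
    stop("components of size 1 are not classifiable")
  sub <- edges[edges$i %in% memberIds & edges$j %in% memberIds, , drop = FALSE]
  nE <- nrow(sub)
  nV <- length(memberIds)
  deg <- table(factor(c(sub$i, sub$j), levels = memberIds))
  if (nE >= nV) "cyclic"
  else if (nE == nV - 1L && all(deg <= 2L)) "linear"
  else "branched"
}

#' Summary metrics of a network
#'
#' @param net an [InteractionNetwork-class]
#' @param damping PageRank damping
#' @return list: densityAll, densityInteracting, averageDegree,
#'   pageRankMeanInteracting, pageRankMeanAll, nNodes, nEdges, nInteracting
#' @export
networkMetrics <- function(net, damping = 0.85) {
  nI <- length(interactingNodes(net))
  prm <- if (length(net@nodes)) pageRankMean(net, damping) else
    list(interacting = NA_real_, all = NA_real_)
  list(
    densityAll = if (length(net@nodes) >= 2L) networkDensity(net, "all")
                 else NA_real_,
    densityInteracting = if (nI >= 2L) networkDensity(net, "interacting")
                         else NA_real_,
    averageDegree = if (length(net@nodes)) averageDegree(net) else NA_real_,
    pageRankMeanInteracting = prm$interacting,
    pageRankMeanAll = prm$all,
    nNodes = length(net@nodes),
    nEdges = nrow(net@edges),
    nInteracting = nI
  )
}
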
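## Generics for the pipeline classes.

#' Number of molecules in a frame
#' @param x a [WaterFrame-class]
#' @return integer count
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' Centers of mass
#'
#' Mass-weighted centers of mass over the massive sites (H_a, O, H_b; the
#' M site is massless).
#'
#' @param x a [WaterFrame-class]
#' @param ... unused
#' @return numeric matrix, one row per molecule, columns x/y/z (nm)
#' @export
setGeneric("com", function(x, ...) standardGeneric("com"))

#' Center-of-mass velocities
#' @param x a [WaterFrame-class]
#' @param ... unused
#' @return numeric matrix, one row per molecule, columns x/y/z (nm/ps)
#' @export
setGeneric("comVelocities", function(x, ...) standardGeneric("comVelocities"))

#' Nodes with at least one edge
#' @param x an [InteractionNetwork-class]
#' @return integer vector of interacting molecule ids
#' @export
setGeneric("interactingNodes", function(x) standardGeneric("interactingNodes"))

#' Convert to an igraph graph
#'
#' Undirected graph whose vertices are the network's node ids (including
#' isolated nodes) and whose edges are the criterion-passing pairs.
#'
#' @param x an [InteractionNetwork-class]
#' @return an \code{igraph} object with vertex attribute \code{name} set to
#'   the molecule ids
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Component-size fractions
#' @param x a [ComponentSizeDistribution-class]
#' @return named numeric vector: fraction n_c(s)/n_components per size s
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
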
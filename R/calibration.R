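## Lambda calibration against a reference cluster-size distribution and
## curve-agreement metrics.

#' MAE and RMSE between two size distributions
#'
#' Aligns the two distributions on the union of their sizes (missing sizes
#' count as 0) and returns the mean absolute error and root-mean-squared
#' error over the aligned values.
#'
#' @param model named vector: size -> fraction (or count)
#' @param reference named vector on the same scale
#' @return named numeric vector c(mae = , rmse = )
#' @export
distributionError <- function(model, reference) {
  if (!length(model) || !length(reference))
    stop("both distributions must be non-empty")
  sizes <- sort(unique(c(as.numeric(names(model)),
                         as.numeric(names(reference)))))
  m <- stats::setNames(rep(0, length(sizes)), sizes)
  r <- m
  m[names(model)] <- as.numeric(model)
  r[names(reference)] <- as.numeric(reference)
  d <- m - r
  c(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Agreement metrics between two sampled curves
#'
#' Coefficient of determination (observed curve as reference), RMSE and
#' MAE of the pointwise residuals.  Curves sampled on different abscissae
#' should be interpolated to a common grid first (see
#' \code{\link[stats]{approx}}).
#'
#' @param observed numeric vector (the reference curve)
#' @param predicted numeric vector of equal length
#' @return list with r_squared, rmse, mae
#' @export
curveAgreement <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) > 0L)
  ssTot <- sum((observed - mean(observed))^2)
  if (ssTot == 0) stop("undefined R^2: observed curve is constant")
  res <- observed - predicted
  list(r_squared = 1 - sum(res^2) / ssTot,
       rmse = sqrt(mean(res^2)),
       mae = mean(abs(res)))
}

## Per-frame groundwork shared by every lambda: cube-filtered nodes,
## cylinder-open candidate pairs, and the lambda-independent energy base
## V_coul + V_LJ + E_kin_pair.
.frameBaseEdges <- function(frame, params, ff, ionsBlock = TRUE) {
  nodes <- innerCubeIds(frame, params@cubeFraction, ff)
  if (length(nodes) < 2L)
    return(list(nodes = nodes, base = numeric(), i = integer(), j = integer()))
  pairs <- candidatePairs(frame, nodes, params@pairCutoff, ff)
  if (!nrow(pairs))
    return(list(nodes = nodes, base = numeric(), i = integer(), j = integer()))
  cm <- com(frame, ff)
  blockers <- cm
  if (ionsBlock && nrow(frame@ions))
    blockers <- rbind(blockers, as.matrix(frame@ions[, c("x", "y", "z")]))
  idxI <- match(pairs[, 1L], frame@ids)
  idxJ <- match(pairs[, 2L], frame@ids)
  open <- logical(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    keep <- rep(TRUE, nrow(blockers))
    keep[c(idxI[p], idxJ[p])] <- FALSE
    open[p] <- !cylinderBlocked(cm[idxI[p], ], cm[idxJ[p], ],
                                blockers[keep, , drop = FALSE], params@rc)
  }
  pairs <- pairs[open, , drop = FALSE]
  if (!nrow(pairs))
    return(list(nodes = nodes, base = numeric(), i = integer(), j = integer()))
  en <- pairEnergies(frame, pairs, ff)
  list(nodes = nodes, base = en$Vcoul + en$VLJ + en$Ekin,
       i = en$i, j = en$j)
}

## Pooled component-size counts at one lambda, given precomputed bases.
.pooledCountsAtLambda <- function(bases, lambda, EkinH) {
  thr <- -lambda * 4 * EkinH
  counts <- integer()
  for (b in bases) {
    if (!length(b$nodes)) next
    sel <- b$base < thr
    g <- igraph::make_empty_graph(n = length(b$nodes), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = as.character(b$nodes))
    if (any(sel))
      g <- igraph::add_edges(g, rbind(as.character(b$i[sel]),
                                      as.character(b$j[sel])))
    sz <- table(igraph::components(g)$csize)
    for (s in names(sz)) {
      counts[s] <- (if (s %in% names(counts)) counts[[s]] else 0L) + sz[[s]]
    }
  }
  counts
}

#' Calibrate the thermal weight lambda
#'
#' For each lambda on the grid, builds the interaction networks of all
#' frames (geometry filters are lambda-independent and computed once),
#' pools the component-size counts, normalizes to fractions and scores
#' them against the reference distribution.  The calibrated lambda* is the
#' MAE-minimizing grid value (ties go to the smallest lambda); RMSE is
#' reported alongside.
#'
#' @param frames list of [WaterFrame-class] objects
#' @param reference named vector: size -> fraction
#' @param grid lambda grid (default 0 to 1 in steps of 0.001)
#' @param params a [CriterionParameters-class]; its lambda slot is ignored
#' @param ff a [ForceField-class]
#' @return a [CalibrationResult-class]
#' @export
calibrateLambda <- function(frames, reference,
                            grid = seq(0, 1, by = 0.001),
                            params, ff = tip4p2005()) {
  if (!length(frames)) stop("at least one frame is required")
  if (!length(grid)) stop("empty lambda grid")
  if (!length(reference)) stop("empty reference distribution")
  bases <- lapply(frames, .frameBaseEdges, params = params, ff = ff)
  mae <- rmse <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    counts <- .pooledCountsAtLambda(bases, grid[gi], params@EkinH)
    frac <- if (length(counts)) counts / sum(counts) else
      stats::setNames(numeric(), character())
    if (!length(frac)) {
      mae[gi] <- rmse[gi] <- Inf
    } else {
      err <- distributionError(frac, reference)
      mae[gi] <- err[["mae"]]
      rmse[gi] <- err[["rmse"]]
    }
  }
  cand <- which(mae == min(mae))
  best <- cand[which.min(grid[cand])]  # ties -> smallest lambda
  new("CalibrationResult", grid = as.numeric(grid), mae = mae, rmse = rmse,
      lambdaStar = as.numeric(grid[best]), maeStar = mae[best],
      rmseStar = rmse[best])
}

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: lambda* = %.3f (MAE = %.6f, RMSE = %.6f) over %d grid points\n",
    object@lambdaStar, object@maeStar, object@rmseStar, length(object@grid)))
  invisible(NULL)
})

#' Read a reference size distribution CSV
#'
#' Two-column CSV with header \code{size,fraction}.
#'
#' @param path file path
#' @return named vector size -> fraction
#' @export
readReferenceDistribution <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("size", "fraction") %in% names(df)))
    stop("reference CSV must have columns 'size' and 'fraction'")
  stats::setNames(df$fraction, df$size)
}
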
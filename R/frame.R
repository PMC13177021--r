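## WaterFrame construction and accessors.

#' Construct a water frame
#'
#' Builds a validated [WaterFrame-class] from per-site position and velocity
#' arrays.  Molecules are wrapped rigidly into the primary box: each
#' molecule is translated by a lattice vector so that its center of mass
#' lies in [0, L) per axis, which keeps the intramolecular geometry intact
#' across the periodic boundary.
#'
#' @param pos numeric array \code{[n, 3, 4]} of site positions (nm); sites
#'   in the order H_a, O, M, H_b
#' @param vel numeric array of the same shape (nm/ps); defaults to zeros
#' @param box edge lengths of the orthorhombic box (nm), length 3 (a single
#'   value is recycled)
#' @param ids integer molecule ids; defaults to \code{seq_len(n)}
#' @param ions data.frame of monatomic ions (columns label, x, y, z, vx,
#'   vy, vz, charge); defaults to none
#' @param temperature,pressure nominal state (K, bar); NA if unknown
#' @param ff force field used for the mass-weighted wrapping
#' @param wrap wrap molecules into the box (default TRUE)
#' @return a [WaterFrame-class]
#' @export
waterFrame <- function(pos, vel = NULL, box, ids = NULL, ions = emptyIons(),
                       temperature = NA_real_, pressure = NA_real_,
                       ff = tip4p2005(), wrap = TRUE) {
  if (is.null(dim(pos)) && length(pos) == 0L) pos <- array(0, c(0L, 3L, 4L))
  stopifnot(length(dim(pos)) == 3L, dim(pos)[2] == 3L, dim(pos)[3] == 4L)
  n <- dim(pos)[1]
  if (is.null(vel)) vel <- array(0, dim(pos))
  box <- rep_len(as.numeric(box), 3L)
  if (is.null(ids)) ids <- seq_len(n)
  storage.mode(pos) <- "double"
  storage.mode(vel) <- "double"
  dimnames(pos) <- dimnames(vel) <- list(NULL, c("x", "y", "z"), .SITES)
  if (wrap && n > 0L) {
    cm <- .comPositions(pos, ff)
    for (ax in 1:3) {
      shift <- -floor(cm[, ax] / box[ax]) * box[ax]
      if (any(shift != 0))
        pos[, ax, ] <- pos[, ax, ] + shift
    }
  }
  new("WaterFrame", box = box, pos = pos, vel = vel,
      ids = as.integer(ids), ions = ions,
      temperature = as.numeric(temperature), pressure = as.numeric(pressure))
}

#' Empty ion table
#' @return zero-row data.frame with the ion columns
#' @export
emptyIons <- function() {
  data.frame(label = character(), x = numeric(), y = numeric(), z = numeric(),
             vx = numeric(), vy = numeric(), vz = numeric(),
             charge = numeric(), stringsAsFactors = FALSE)
}

#' @describeIn waterFrame number of molecules
#' @param x a [WaterFrame-class]
#' @export
setMethod("nMolecules", "WaterFrame", function(x) length(x@ids))

#' @rdname com
#' @param ff force field supplying the site masses
setMethod("com", "WaterFrame", function(x, ff = tip4p2005()) {
  m <- .comPositions(x@pos, ff)
  rownames(m) <- x@ids
  m
})

#' @rdname comVelocities
#' @param ff force field supplying the site masses
setMethod("comVelocities", "WaterFrame", function(x, ff = tip4p2005()) {
  m <- .comPositions(x@vel, ff)
  rownames(m) <- x@ids
  m
})

#' Extract one molecule from a frame
#'
#' @param frame a [WaterFrame-class]
#' @param id molecule id
#' @param ff force field for the COM fields
#' @return list with elements \code{id}, \code{pos} and \code{vel} (3 x 4
#'   matrices, columns H_a, O, M, H_b), \code{com} and \code{comVel}
#' @export
molecule <- function(frame, id, ff = tip4p2005()) {
  k <- match(id, frame@ids)
  if (is.na(k)) stop("no molecule with id ", id)
  p <- frame@pos[k, , ]  # 3 x 4 (axis x site)
  v <- frame@vel[k, , ]
  w <- c(ff@mH, ff@mO, 0, ff@mH) / waterMass(ff)
  list(id = id, pos = p, vel = v,
       com = as.numeric(p %*% w), comVel = as.numeric(v %*% w))
}

setMethod("show", "WaterFrame", function(object) {
  cat(sprintf("WaterFrame: %d water molecules, %d ions\n",
              nMolecules(object), nrow(object@ions)))
  cat(sprintf("  box: %.4f x %.4f x %.4f nm\n",
              object@box[1], object@box[2], object@box[3]))
  if (!is.na(object@temperature) || !is.na(object@pressure))
    cat(sprintf("  state: T = %s K, P = %s bar\n",
                format(object@temperature), format(object@pressure)))
  invisible(NULL)
})
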
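## Fixed-width (GRO dialect) frame reading and writing.
##
## Layout per atom line: %5d residue id, %-5s residue name, %5s atom name,
## %5d atom index, 3 x %8.3f position (nm), optionally 3 x %8.4f velocity
## (nm/ps).  Water residues have exactly 4 sites; monatomic residues are
## read as ions.

.DEFAULT_ION_CHARGES <- c(CL = -1, NA. = +1, K = +1, LI = +1,
                          MG = +2, CA = +2, BR = -1, F = -1, I = -1)

.ionCharge <- function(label, charges = .DEFAULT_ION_CHARGES) {
  key <- toupper(gsub("[^A-Za-z].*$", "", label))
  if (key == "NA") key <- "NA."  # sodium; avoid the reserved name
  if (key %in% names(charges)) unname(charges[key]) else NA_real_
}

## Site order within a residue, detected from atom names.  Returns the
## permutation mapping file order -> (Ha, O, M, Hb).
.siteOrder <- function(atomNames, override = NULL) {
  if (!is.null(override)) return(override)
  up <- toupper(atomNames)
  o <- grep("^O", up)
  h <- grep("^H", up)
  m <- grep("^M", up)
  if (length(o) == 1L && length(h) == 2L && length(m) == 1L)
    return(c(h[1L], o, m, h[2L]))
  stop("cannot detect site order from atom names: ",
       paste(atomNames, collapse = ", "))
}

#' Read a fixed-width frame file
#'
#' Parses a GRO-dialect coordinate file into a [WaterFrame-class].  Atoms
#' are grouped by residue: 4-site residues become water molecules (site
#' order H_a/O/M/H_b or O/H/H/M, auto-detected from the atom names),
#' 1-site residues become ions with charges looked up from
#' \code{ionCharges}.  Missing velocity columns are read as zero vectors
#' with a warning.
#'
#' @param path file path
#' @param ff force field (for COM-based rigid wrapping)
#' @param siteOrder optional integer permutation overriding atom-name
#'   detection (file order to H_a, O, M, H_b)
#' @param ionCharges named numeric vector of charges by element symbol
#'   (sodium under the key \code{"NA."})
#' @param wrap wrap molecules into the box (default TRUE)
#' @return a [WaterFrame-class]
#' @seealso [writeGro()]
#' @export
readGro <- function(path, ff = tip4p2005(), siteOrder = NULL,
                    ionCharges = .DEFAULT_ION_CHARGES, wrap = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated frame file: ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(natoms)) stop("unreadable atom count on line 2")
  if (length(lines) < 3L + natoms)
    stop("atom count mismatch: header declares ", natoms, " atoms, file has ",
         length(lines) - 3L, " atom lines")
  atomLines <- lines[seq.int(3L, length.out = natoms)]
  boxFields <- as.numeric(strsplit(trimws(lines[3L + natoms]), "\\s+")[[1L]])
  if (length(boxFields) > 3L && any(boxFields[-(1:3)] != 0))
    stop("unsupported format: non-orthorhombic (triclinic) box")
  box <- boxFields[1:3]

  resid <- as.integer(substr(atomLines, 1L, 5L))
  resname <- trimws(substr(atomLines, 6L, 10L))
  atomname <- trimws(substr(atomLines, 11L, 15L))
  hasVel <- all(nchar(atomLines) >= 68L)
  num <- function(from, to) as.numeric(substr(atomLines, from, to))
  xyz <- cbind(num(21L, 28L), num(29L, 36L), num(37L, 44L))
  if (anyNA(xyz)) stop("unreadable coordinates in atom records")
  if (hasVel) {
    vxyz <- cbind(num(45L, 52L), num(53L, 60L), num(61L, 68L))
    if (anyNA(vxyz)) stop("unreadable velocities in atom records")
  } else {
    warning("no velocity columns; velocities set to zero")
    vxyz <- matrix(0, natoms, 3L)
  }

  ## group contiguous runs of identical residue ids
  runs <- rle(resid)
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  sizes <- runs$lengths
  if (any(!sizes %in% c(1L, 4L)))
    stop("format error: residue with ", sizes[which(!sizes %in% c(1L, 4L))[1L]],
         " sites (expected 1 or 4)")

  wat <- which(sizes == 4L)
  n <- length(wat)
  pos <- array(0, c(n, 3L, 4L))
  vel <- array(0, c(n, 3L, 4L))
  ids <- integer(n)
  for (k in seq_along(wat)) {
    rows <- seq.int(starts[wat[k]], length.out = 4L)
    perm <- .siteOrder(atomname[rows], siteOrder)
    pos[k, , ] <- t(xyz[rows, , drop = FALSE][perm, , drop = FALSE])
    vel[k, , ] <- t(vxyz[rows, , drop = FALSE][perm, , drop = FALSE])
    ids[k] <- runs$values[wat[k]]
  }

  ion <- which(sizes == 1L)
  ions <- if (length(ion)) {
    rows <- starts[ion]
    data.frame(label = resname[rows],
               x = xyz[rows, 1L], y = xyz[rows, 2L], z = xyz[rows, 3L],
               vx = vxyz[rows, 1L], vy = vxyz[rows, 2L], vz = vxyz[rows, 3L],
               charge = vapply(resname[rows], .ionCharge, numeric(1L),
                               charges = ionCharges),
               stringsAsFactors = FALSE, row.names = NULL)
  } else emptyIons()

  waterFrame(pos, vel, box = box, ids = ids, ions = ions, ff = ff, wrap = wrap)
}

#' Write a frame as a fixed-width frame file
#'
#' Emits the same dialect [readGro()] consumes: positions at %8.3f nm,
#' velocities at %8.4f nm/ps, water residues named SOL with atom names
#' HW1/OW/MW/HW2, ions as single-atom residues.
#'
#' @param frame a [WaterFrame-class]
#' @param path output file path
#' @param title title line content
#' @return the path, invisibly
#' @export
writeGro <- function(frame, path, title = "four-site water frame") {
  if (length(frame@box) != 3L)
    stop("unsupported format: only orthorhombic boxes can be written")
  con <- file(path, "w")
  on.exit(close(con))
  n <- nMolecules(frame)
  ni <- nrow(frame@ions)
  writeLines(c(title, sprintf("%5d", 4L * n + ni)), con)
  atomNames <- c("HW1", "OW", "MW", "HW2")
  idx <- 0L
  if (n > 0L) {
    lines <- character(4L * n)
    for (k in seq_len(n)) {
      for (s in 1:4) {
        idx <- idx + 1L
        lines[idx] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
          frame@ids[k] %% 100000L, "SOL", atomNames[s], idx %% 100000L,
          frame@pos[k, 1L, s], frame@pos[k, 2L, s], frame@pos[k, 3L, s],
          frame@vel[k, 1L, s], frame@vel[k, 2L, s], frame@vel[k, 3L, s])
      }
    }
    writeLines(lines, con)
  }
  if (ni > 0L) {
    residBase <- if (n > 0L) max(frame@ids) else 0L
    for (r in seq_len(ni)) {
      idx <- idx + 1L
      io <- frame@ions[r, ]
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
        (residBase + r) %% 100000L, io$label, io$label, idx %% 100000L,
        io$x, io$y, io$z, io$vx, io$vy, io$vz), con)
    }
  }
  writeLines(sprintf("%10.5f%10.5f%10.5f",
                     frame@box[1], frame@box[2], frame@box[3]), con)
  invisible(path)
}
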
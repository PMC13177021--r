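## QTAIM bond-critical-point (BCP) property tables: reading, derived
## energy densities, interaction classification, group comparison.
##
## All quantities are in atomic units.  Identities used throughout:
##   V = -G - K      (potential energy density)
##   H = G + V = -K  (total energy density)
##   ratio = -G / V  (kinetic/potential balance)

#' Potential energy density at a critical point
#'
#' \eqn{V(r) = -G(r) - K(r)}: the local potential implied by the
#' Lagrangian (G, always >= 0) and Hamiltonian (K) kinetic energy
#' densities.
#'
#' @param G Lagrangian kinetic energy density (a.u.), >= 0
#' @param K Hamiltonian kinetic energy density (a.u.)
#' @return V (a.u.)
#' @export
potentialEnergyDensity <- function(G, K) {
  if (any(G < 0)) stop("G must be non-negative")
  -G - K
}

#' Classify a bond critical point
#'
#' Sign-based rule: \code{noncovalent} when the Laplacian and the total
#' energy density H are both positive (density depletion, kinetic
#' dominance); \code{partially_covalent} when the Laplacian is positive
#' but H < 0; \code{covalent} when both are negative.  Records with a
#' zero Laplacian or zero H fall back to the -G/V ratio (> 1 noncovalent;
#' (0.5, 1] partially covalent; <= 0.5 covalent).  The physically
#' inconsistent combination (Laplacian < 0 with H > 0) is labelled NA and
#' flagged rather than raised.
#'
#' @param laplacian del^2 rho (a.u.); vectorized
#' @param G,V kinetic and potential energy densities (a.u.)
#' @return data.frame with columns label (character, NA when
#'   inconsistent) and inconsistent (logical)
#' @export
classifyBcp <- function(laplacian, G, V) {
  H <- G + V
  ratio <- -G / V
  n <- length(H)
  label <- rep(NA_character_, n)
  inconsistent <- rep(FALSE, n)
  for (r in seq_len(n)) {
    if (laplacian[r] > 0 && H[r] > 0) label[r] <- "noncovalent"
    else if (laplacian[r] > 0 && H[r] < 0) label[r] <- "partially_covalent"
    else if (laplacian[r] < 0 && H[r] < 0) label[r] <- "covalent"
    else if (laplacian[r] < 0 && H[r] > 0) inconsistent[r] <- TRUE
    else {
      ## boundary case (zero laplacian or zero H): ratio rule
      label[r] <- if (ratio[r] > 1) "noncovalent"
                  else if (ratio[r] > 0.5) "partially_covalent"
                  else "covalent"
    }
  }
  data.frame(label = label, inconsistent = inconsistent)
}

#' Read a BCP property table
#'
#' Delimited text (comma or tab, auto-detected) with a header naming a
#' subset of \code{rho}, \code{laplacian}, \code{G}, \code{K}, \code{V};
#' at least rho, laplacian, G and one of K or V are required.  The
#' missing member of \{K, V\} is derived from V = -G - K; when all three
#' are supplied they must satisfy the identity to within \code{tol}.
#' Derived columns H = G + V, ratio = -G/V, and the classification label
#' are appended.
#'
#' @param path file path
#' @param tol consistency tolerance on |G + K + V| (default 1e-8)
#' @return data.frame with columns rho, laplacian, G, K, V, H, ratio,
#'   label, inconsistent
#' @export
readBcpTable <- function(path, tol = 1e-8) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  bcpTable(df, tol = tol)
}

#' Validate and complete a BCP data.frame
#'
#' @param df data.frame with columns among rho, laplacian, G, K, V
#' @param tol consistency tolerance
#' @return completed data.frame (see [readBcpTable()])
#' @export
bcpTable <- function(df, tol = 1e-8) {
  need <- c("rho", "laplacian", "G")
  if (!all(need %in% names(df)))
    stop("BCP table must contain columns rho, laplacian, G")
  if (!any(c("K", "V") %in% names(df)))
    stop("BCP table must contain K or V")
  if (any(df$G < 0)) stop("invalid BCP record: G must be >= 0")
  if (!"V" %in% names(df)) df$V <- potentialEnergyDensity(df$G, df$K)
  if (!"K" %in% names(df)) df$K <- -df$G - df$V
  bad <- abs(df$G + df$K + df$V) > tol
  if (any(bad))
    stop("inconsistent (G, K, V) triple in row(s) ",
         paste(which(bad), collapse = ", "),
         ": V = -G - K violated beyond tolerance")
  df$H <- df$G + df$V
  df$ratio <- -df$G / df$V
  cl <- classifyBcp(df$laplacian, df$G, df$V)
  df$label <- cl$label
  df$inconsistent <- cl$inconsistent
  df[, c("rho", "laplacian", "G", "K", "V", "H", "ratio", "label",
         "inconsistent",
         setdiff(names(df), c("rho", "laplacian", "G", "K", "V", "H",
                              "ratio", "label", "inconsistent")))]
}

#' Write a BCP table as CSV
#'
#' @param df a BCP data.frame
#' @param path output path
#' @return the path, invisibly
#' @export
writeBcpTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Class percentages per group
#'
#' Percentage of each interaction class, overall or per grouping factor
#' (e.g. component type); percentages sum to 100 within each group.
#'
#' @param labels character vector of class labels
#' @param groups optional grouping vector of the same length
#' @return data.frame with columns group, label, percent
#' @export
summarizeClasses <- function(labels, groups = NULL) {
  if (!length(labels)) stop("no records to summarize")
  if (is.null(groups)) groups <- rep("all", length(labels))
  stopifnot(length(groups) == length(labels))
  parts <- split(labels, groups)
  out <- do.call(rbind, lapply(names(parts), function(gname) {
    l <- parts[[gname]]
    tab <- table(l)
    data.frame(group = gname, label = names(tab),
               percent = 100 * as.numeric(tab) / length(l),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Omnibus comparison of a property across conditions
#'
#' Kruskal-Wallis rank-sum test by default (robust to non-normality);
#' one-way ANOVA selectable.  Degenerate input (every observation
#' identical) returns p = 1 with a warning.
#'
#' @param values list of numeric vectors, one per condition (>= 2 groups,
#'   each with >= 2 observations)
#' @param method "kruskal" or "anova"
#' @return list with p.value, method, statistic
#' @export
compareGroups <- function(values, method = c("kruskal", "anova")) {
  method <- match.arg(method)
  if (length(values) < 2L) stop("at least 2 groups are required")
  if (any(vapply(values, length, integer(1L)) < 2L))
    stop("each group needs at least 2 observations")
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(seq_along(values), vapply(values, length, integer(1L))))
  if (length(unique(x)) == 1L) {
    warning("all observations identical across groups; p = 1")
    return(list(p.value = 1, method = method, statistic = NA_real_))
  }
  if (method == "kruskal") {
    kt <- stats::kruskal.test(x, g)
    list(p.value = unname(kt$p.value), method = "kruskal",
         statistic = unname(kt$statistic))
  } else {
    fit <- stats::aov(x ~ g)
    s <- summary(fit)[[1L]]
    list(p.value = s[["Pr(>F)"]][1L], method = "anova",
         statistic = s[["F value"]][1L])
  }
}
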
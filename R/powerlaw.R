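## Power-law model of the component-size distribution.

#' Fit n_c(s) = A * s^b
#'
#' Ordinary least squares of log n_c(s) on log s over sizes with positive
#' counts.  A = exp(intercept) is the model value at s = 1 (the monomer
#' count under the model); b is the slope.  A weighted variant
#' (weights = counts) is selectable, and the fit can be performed on
#' normalized fractions instead of raw counts (b is unchanged; A rescales).
#'
#' @param dist a [ComponentSizeDistribution-class], or a named vector
#'   size -> count
#' @param weighted logical; weight the regression by the counts
#' @param normalized logical; fit fractions n_c(s)/n_components instead of
#'   raw counts
#' @return a [PowerLawFit-class]
#' @examples
#' d <- componentSizeCounts(c(`1` = 48, `2` = 12, `3` = 5, `4` = 3))
#' fitPowerLaw(d)
#' @export
fitPowerLaw <- function(dist, weighted = FALSE, normalized = FALSE) {
  if (is(dist, "ComponentSizeDistribution")) {
    s <- dist@sizes
    y <- as.numeric(dist@counts)
    if (normalized) y <- y / dist@nComponents
  } else {
    s <- as.numeric(names(dist))
    y <- as.numeric(dist)
    if (normalized) y <- y / sum(y)
  }
  keep <- y > 0
  s <- s[keep]; y <- y[keep]
  if (length(unique(s)) < 2L)
    stop("insufficient data: need at least 2 distinct sizes with positive counts")
  w <- if (weighted) y else NULL
  fit <- stats::lm(log(y) ~ log(s), weights = w)
  ## R^2 computed directly (summary.lm warns on numerically perfect fits)
  ly <- log(y)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  new("PowerLawFit",
      A = exp(unname(stats::coef(fit)[1L])),
      b = unname(stats::coef(fit)[2L]),
      rSquared = r2)
}

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: n_c(s) = %.4g * s^(%.4f)   [log-log R^2 = %.4f]\n",
              object@A, object@b, object@rSquared))
  invisible(NULL)
})

#' Evaluate a power-law fit
#'
#' @param fit a [PowerLawFit-class]
#' @param s sizes at which to evaluate
#' @return model values A * s^b
#' @export
predictPowerLaw <- function(fit, s) fit@A * s^fit@b
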
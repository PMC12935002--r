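clamp01 <- function(x) pmin(1, pmax(0, x))

# keep stochastic oxidation draws inside [0, 1] without creating a point
# mass at the boundary: reflect overshoot back into the interval
reflect01 <- function(x) {
  x <- ifelse(x < 0, -x, x)
  x <- ifelse(x > 1, 2 - x, x)
  clamp01(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)  # x first: keeps dim attributes

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name, lo, hi), call. = FALSE)
  invisible(x)
}

#' Ashman's D separation statistic for two Gaussian modes
#'
#' Dimensionless separation between two modes,
#' \eqn{D = |\mu_1-\mu_2| / \sqrt{(\sigma_1^2+\sigma_2^2)/2}}. Values above
#' roughly 2 indicate modes distinguishable as a bimodal distribution.
#'
#' @param mu1,mu2 component means.
#' @param sd1,sd2 component standard deviations.
#' @return numeric scalar.
#' @export
ashman_d <- function(mu1, mu2, sd1, sd2) {
  abs(mu1 - mu2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Significance stars for a p-value
#'
#' Default thresholds follow the strain-comparison convention used throughout
#' the package: * p < 0.05, ** p < 0.001, *** p < 0.0001.
#'
#' @param p p-value(s).
#' @param thresholds decreasing vector of p cutoffs for *, **, ***.
#' @return character vector of star annotations ("ns" when above all cutoffs).
#' @export
p_stars <- function(p, thresholds = c(0.05, 0.001, 1e-4)) {
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) < 0))
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < thresholds[3]) "***"
    else if (pi < thresholds[2]) "**"
    else if (pi < thresholds[1]) "*"
    else "ns"
  }, character(1))
}
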
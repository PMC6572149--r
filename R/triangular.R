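# Triangular distribution on [lower, upper] with mode `mode`.
# Used for expert-elicited influencing-factor scores. Degenerate
# point masses (lower == upper) are supported so that fixed scores can be
# expressed in the same interface.

.check_tri <- function(lower, mode, upper) {
  if (any(is.na(c(lower, mode, upper)))) {
    stop("triangular parameters must not be NA", call. = FALSE)
  }
  if (lower > mode || mode > upper) {
    stop(sprintf("invalid triangular parameters: need lower <= mode <= upper, got [%g, %g, %g]",
                 lower, mode, upper), call. = FALSE)
  }
}

#' The triangular distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the triangular distribution with support `[lower, upper]` and mode
#' `mode`. The default mode is the midpoint (symmetric triangular), whose
#' mean `(lower + mode + upper) / 3` then equals the midpoint and whose
#' variance is `(upper - lower)^2 / 24`.
#'
#' A degenerate distribution (`lower == upper`) is accepted and behaves as a
#' point mass.
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param lower,upper Support bounds, `lower <= upper`.
#' @param mode Mode of the density, in `[lower, upper]`; defaults to the
#'   midpoint.
#' @return `dtri` gives the density, `ptri` the CDF, `qtri` the quantile
#'   function and `rtri` random deviates.
#' @examples
#' qtri(0.5, 3, 10)          # median of symmetric triangular on [3, 10]
#' mean(rtri(1e4, 3, 10))    # ~ 6.5
#' @export
dtri <- function(x, lower, upper, mode = (lower + upper) / 2) {
  .check_tri(lower, mode, upper)
  if (lower == upper) return(ifelse(x == lower, Inf, 0))
  d <- numeric(length(x))
  w <- upper - lower
  up <- x >= lower & x <= mode
  dn <- x > mode & x <= upper
  if (mode > lower) d[up] <- 2 * (x[up] - lower) / (w * (mode - lower))
  else d[up] <- 2 / w  # left edge of a left-degenerate triangle
  if (upper > mode) d[dn] <- 2 * (upper - x[dn]) / (w * (upper - mode))
  d
}

#' @rdname dtri
#' @export
ptri <- function(q, lower, upper, mode = (lower + upper) / 2) {
  .check_tri(lower, mode, upper)
  if (lower == upper) return(as.numeric(q >= lower))
  w <- upper - lower
  p <- numeric(length(q))
  p[q >= upper] <- 1
  up <- q > lower & q <= mode
  dn <- q > mode & q < upper
  if (mode > lower) p[up] <- (q[up] - lower)^2 / (w * (mode - lower))
  if (upper > mode) p[dn] <- 1 - (upper - q[dn])^2 / (w * (upper - mode))
  if (upper == mode) p[q == mode] <- 1
  p
}

#' @rdname dtri
#' @export
qtri <- function(p, lower, upper, mode = (lower + upper) / 2) {
  .check_tri(lower, mode, upper)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (lower == upper) return(rep(lower, length(p)))
  w <- upper - lower
  fc <- (mode - lower) / w   # CDF at the mode
  q <- numeric(length(p))
  lo <- p <= fc
  q[lo] <- lower + sqrt(p[lo] * w * (mode - lower))
  q[!lo] <- upper - sqrt((1 - p[!lo]) * w * (upper - mode))
  q
}

#' @rdname dtri
#' @export
rtri <- function(n, lower, upper, mode = (lower + upper) / 2) {
  qtri(runif(n), lower, upper, mode)
}

# closed-form moments, used for analytic checks and triangular-mean
# evaluation of the correction factor
tri_mean <- function(lower, upper, mode = (lower + upper) / 2) {
  (lower + mode + upper) / 3
}

tri_var <- function(lower, upper, mode = (lower + upper) / 2) {
  (lower^2 + mode^2 + upper^2 - lower * mode - lower * upper - mode * upper) / 18
}
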
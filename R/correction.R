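# The eight-factor probability correction model. Raw behavior frequencies
# P' are multiplied by a correction factor
#
#   F(x) = intercept - slope * [ (wa*a + wb*b + wc*c) + (d+e+f)/3 + (g+h)/2 ]
#
# where a..c are organizational factors (rules and regulations, education
# and training, safety reward), d..f human-machine factors (workload,
# device, working environment) and g..h personal factors (safety
# physiology/psychology, skills and knowledge). Each factor is a
# dimensionless score in [0, 10] — larger is worse — elicited as a
# triangular distribution. With the default coefficients
# (weights 0.2/0.6/0.2, slope 0.0167, intercept 1.5) F lies in
# [0.999, 1.5] and decreases in every factor.

.factor_names <- letters[1:8]

#' Coefficients of the correction-factor model
#'
#' @param org_weights Weights of the three organizational factors a, b, c;
#'   must sum to 1. Defaults to `c(0.2, 0.6, 0.2)`. The human-machine and
#'   personal groups enter as unweighted means.
#' @param slope Multiplier of the grouped factor score (default 0.0167).
#' @param intercept Value of F when all factors score 0 (default 1.5).
#' @return An object of class `model_coefficients`.
#' @export
model_coefficients <- function(org_weights = c(0.2, 0.6, 0.2),
                               slope = 0.0167, intercept = 1.5) {
  if (length(org_weights) != 3 || abs(sum(org_weights) - 1) > 1e-8) {
    stop("org_weights must be three weights summing to 1", call. = FALSE)
  }
  structure(list(org_weights = unname(org_weights),
                 slope = slope, intercept = intercept),
            class = "model_coefficients")
}

# per-factor linear weights implied by the grouped means
.factor_weights <- function(coeffs) {
  c(coeffs$org_weights, rep(1 / 3, 3), rep(1 / 2, 2))
}

.check_factor_values <- function(values) {
  if (is.null(names(values)) || !all(.factor_names %in% names(values))) {
    missing <- setdiff(.factor_names, names(values))
    stop("missing factor value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- values[.factor_names]
  if (any(!is.finite(v)) || any(v < 0 | v > 10)) {
    stop("factor values must be finite scores in [0, 10]", call. = FALSE)
  }
  v
}

#' Correction factor for unsafe-behavior probabilities
#'
#' Evaluates the revision factor F at a set of influencing-factor scores.
#' F multiplies a raw occurrence probability (see [revised_probability()]);
#' because the intercept is 1.5, well-scored contexts still inflate raw
#' frequencies (F > 1), reflecting under-reporting of unsafe behavior in
#' accident records.
#'
#' @param values Named numeric vector with entries `a` through `h`, each a
#'   score in \[0, 10\].
#' @param coeffs A [model_coefficients()] object.
#' @return The dimensionless correction factor F.
#' @examples
#' correction_factor(c(a = 0.5, b = 0.5, c = 6.5, d = 6.5,
#'                     e = 0.5, f = 6.5, g = 2, h = 0.5))  # 1.376
#' @export
correction_factor <- function(values, coeffs = model_coefficients()) {
  v <- .check_factor_values(values)
  score <- sum(v * .factor_weights(coeffs))
  coeffs$intercept - coeffs$slope * score
}

# vectorized evaluation over an n x 8 sample matrix (columns a..h)
.correction_factor_matrix <- function(samples, coeffs) {
  w <- .factor_weights(coeffs)
  coeffs$intercept - coeffs$slope * drop(samples[, .factor_names, drop = FALSE] %*% w)
}

#' Factor profile of a working type
#'
#' Bundles the eight triangular factor ranges of one working type. Ranges
#' are given as `[lower, upper]` (mode defaulting to the midpoint, i.e. a
#' symmetric triangular) or `[lower, mode, upper]`.
#'
#' @param working_type Working type id the profile belongs to.
#' @param ranges Named list with entries `a` through `h`, each a numeric
#'   vector of length 2 or 3, scores within \[0, 10\].
#' @return An object of class `factor_profile`: a data frame with columns
#'   `factor`, `lower`, `mode`, `upper` and attribute `working_type`.
#' @examples
#' factor_profile("ventilation",
#'   list(a = c(0, 1), b = c(0, 1), c = c(3, 10), d = c(3, 10),
#'        e = c(0, 1), f = c(3, 10), g = c(1, 3), h = c(0, 1)))
#' @export
factor_profile <- function(working_type, ranges) {
  if (!setequal(names(ranges), .factor_names)) {
    stop("ranges must name each of the eight factors a-h exactly once",
         call. = FALSE)
  }
  rows <- lapply(.factor_names, function(f) {
    r <- ranges[[f]]
    if (!length(r) %in% 2:3 || any(!is.finite(r))) {
      stop(sprintf("factors.%s: range must be [lower, upper] or [lower, mode, upper]", f),
           call. = FALSE)
    }
    lower <- r[1]
    upper <- r[length(r)]
    mode <- if (length(r) == 3) r[2] else (lower + upper) / 2
    if (lower < 0 || upper > 10 || lower > mode || mode > upper) {
      stop(sprintf("factors.%s: need 0 <= lower <= mode <= upper <= 10, got [%s]",
                   f, paste(r, collapse = ", ")), call. = FALSE)
    }
    data.frame(factor = f, lower = lower, mode = mode, upper = upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("factor_profile", "data.frame"),
            working_type = working_type)
}

#' Correction factor at the triangular means of a profile
#'
#' Evaluates the correction factor with every factor fixed at its triangular
#' mean `(lower + mode + upper) / 3`. Because F is linear in the factors
#' this equals the expectation of F under independent triangular sampling,
#' and with default (symmetric) modes it equals F at the range midpoints.
#'
#' @param profile A [factor_profile()].
#' @param coeffs A [model_coefficients()] object.
#' @return The mean correction factor F-bar.
#' @export
correction_factor_mean <- function(profile, coeffs = model_coefficients()) {
  means <- tri_mean(profile$lower, profile$upper, profile$mode)
  correction_factor(setNames(means, profile$factor), coeffs)
}

#' Sample influencing factors from a profile
#'
#' Draws independent triangular deviates for each of the eight factors.
#' Identical `(profile, n, seed)` yield bitwise-identical samples.
#'
#' @param profile A [factor_profile()].
#' @param n Number of draws per factor (`n >= 1`).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An `n` x 8 numeric matrix with columns `a` through `h`.
#' @export
sample_factors <- function(profile, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  draw <- function() {
    cols <- lapply(seq_len(nrow(profile)), function(i) {
      rtri(n, profile$lower[i], profile$upper[i], profile$mode[i])
    })
    m <- do.call(cbind, cols)
    colnames(m) <- profile$factor
    m
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Revise a raw occurrence probability
#'
#' Applies the correction factor: P = P' * F. Products exceeding 1 are
#' clamped to 1 with a warning, so the result remains a probability.
#'
#' @param p_raw Raw occurrence probability (or vector of them), in \[0, 1\].
#' @param F Correction factor(s), positive.
#' @return The revised probability, same length as the longer argument.
#' @examples
#' revised_probability(0.16, 1.3756)  # ~ 0.22
#' @export
revised_probability <- function(p_raw, F) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop("p_raw must lie in [0, 1]", call. = FALSE)
  }
  if (any(F <= 0, na.rm = TRUE)) {
    stop("correction factor F must be positive", call. = FALSE)
  }
  p <- p_raw * F
  if (any(p > 1, na.rm = TRUE)) {
    warning("revised probability exceeded 1 and was clamped", call. = FALSE)
    p <- pmin(p, 1)
  }
  p
}
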
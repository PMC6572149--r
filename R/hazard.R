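# Accident-hazard quantification. The hazard index I = B * C combines a
# possibility grade B (how likely an unsafe behavior is to trigger an
# accident) with a severity grade C (how bad the consequence is, scored
# 1-5 against injury and economic-loss bands). Per (working type, behavior)
# cell the elicited index is modelled as a normal distribution.

.possibility_scores <- c(1, 0.5, 0.1, 0.05, 0.01)

#' Possibility grades of accident occurrence
#'
#' Five-grade scale for the possibility score B that an unsafe behavior
#' causes an accident.
#'
#' @return A data frame with columns `label` and `score`.
#' @export
possibility_grades <- function() {
  data.frame(label = c("very likely", "probably", "occasionally",
                       "unlikely", "scarcely possible"),
             score = .possibility_scores,
             stringsAsFactors = FALSE)
}

#' Severity grades of accident consequences
#'
#' Five-grade scale for the severity score C, aligned with injury degree and
#' economic-loss bands (CNY); the loss bands are documentation, only the
#' ordinal score enters the hazard index.
#'
#' @return A data frame with columns `degree`, `economic_loss_cny` and
#'   `score`.
#' @export
severity_grades <- function() {
  data.frame(
    degree = c("one person slightly injured",
               "more than one person slightly injured",
               "more than one person seriously injured",
               "one person died",
               "more than one person died"),
    economic_loss_cny = c("< 2,000", "2,000 - 10,000", "10,000 - 1,000,000",
                          "1,000,000 - 5,000,000", "> 5,000,000"),
    score = 1:5,
    stringsAsFactors = FALSE)
}

#' Accident hazard index
#'
#' The hazard index I = B * C. By default the scores must come from the
#' grade tables ([possibility_grades()], [severity_grades()]); in
#' permissive mode any B in (0, 1\] and C in \[1, 5\] are accepted, e.g. for
#' interpolated expert scores.
#'
#' @param B Possibility score(s).
#' @param C Severity score(s).
#' @param permissive Accept off-grade scores within the valid ranges.
#' @return The hazard index, in \[0.01, 5\] for graded inputs.
#' @examples
#' hazard_index(0.5, 4)
#' @export
hazard_index <- function(B, C, permissive = FALSE) {
  if (permissive) {
    if (any(B <= 0 | B > 1)) stop("B must lie in (0, 1]", call. = FALSE)
    if (any(C < 1 | C > 5)) stop("C must lie in [1, 5]", call. = FALSE)
  } else {
    if (!all(B %in% .possibility_scores)) {
      stop("B must be a possibility grade score (1, 0.5, 0.1, 0.05, 0.01)",
           call. = FALSE)
    }
    if (!all(C %in% 1:5)) {
      stop("C must be a severity grade score (1, 2, 3, 4, 5)", call. = FALSE)
    }
  }
  B * C
}

#' Hazard-index specification for one table cell
#'
#' Normal-distribution parameters of the accident hazard index for one
#' (working type, behavior class) cell.
#'
#' @param working_type Working type id.
#' @param behavior Behavior class code.
#' @param mean Mean hazard index, positive.
#' @param sd Standard deviation, non-negative (zero gives a degenerate,
#'   deterministic index).
#' @return An object of class `hazard_spec`.
#' @export
hazard_spec <- function(working_type, behavior, mean, sd) {
  .check_tokens(working_type, .working_type_ids, "working type")
  .check_tokens(behavior, .behavior_codes, "behavior code")
  if (!is.finite(mean) || mean <= 0) stop("hazard mean must be positive", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("hazard sd must be non-negative", call. = FALSE)
  structure(list(working_type = working_type, behavior = behavior,
                 mean = mean, sd = sd),
            class = "hazard_spec")
}

# Inverse-CDF hazard draw shared by the sampler and the Monte Carlo engine:
# feeding the same uniforms through different specs yields comonotonic
# indices across behavior cells.
.hazard_quantile <- function(u, mean, sd,
                             truncation = c("none", "resample", "clip")) {
  truncation <- match.arg(truncation)
  if (sd == 0) return(rep(mean, length(u)))
  switch(truncation,
    none = qnorm(u, mean, sd),
    # lower truncation at zero via the conditional quantile, so shared
    # uniforms stay usable and determinism is preserved
    resample = {
      p0 <- pnorm(0, mean, sd)
      qnorm(p0 + u * (1 - p0), mean, sd)
    },
    clip = pmax(qnorm(u, mean, sd), 0))
}

#' Sample the accident hazard index
#'
#' Normal draws from a [hazard_spec()], with an optional positivity policy:
#' `"none"` (raw normal, the default — matching untruncated moment
#' propagation), `"resample"` (exact lower truncation at zero, implemented
#' by conditional inverse-CDF so identical seeds give identical draws), or
#' `"clip"` (negative draws set to zero).
#'
#' @param spec A [hazard_spec()] (or any list with `mean` and `sd`).
#' @param n Number of draws (`n >= 1`).
#' @param seed Optional integer seed.
#' @param truncation Positivity policy.
#' @return Numeric vector of `n` hazard-index draws.
#' @export
sample_hazard_index <- function(spec, n, seed = NULL,
                                truncation = c("none", "resample", "clip")) {
  truncation <- match.arg(truncation)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  draw <- function() .hazard_quantile(runif(n), spec$mean, spec$sd, truncation)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
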
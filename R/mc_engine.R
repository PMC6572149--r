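# Monte Carlo propagation of R = P * I. Each iteration draws the eight
# influencing factors (triangular), forms the correction factor F and the
# revised probability P = P' * F, draws the hazard index I (normal), and
# multiplies. Factor draws are shared across the behavior classes of a
# working type within an iteration — the factors describe one
# miner-population context per scenario — while hazard draws are
# per-behavior, either comonotonic (one shared uniform stream, the default,
# which makes the total's SD approximately the sum of component SDs) or
# independent.

#' Simulation settings
#'
#' @param iterations Number of Monte Carlo iterations (default 10,000).
#' @param seed Integer seed driving all randomness of a run.
#' @param confidence Level of the percentile interval reported with each
#'   risk distribution (default 0.95, i.e. the 2.5%-97.5% band).
#' @param truncation Hazard positivity policy, see [sample_hazard_index()].
#' @param total_mode How per-behavior risks are coupled when totalled:
#'   `"comonotonic"` (shared hazard uniform stream; default) or
#'   `"independent"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(iterations = 10000, seed = 1L, confidence = 0.95,
                       truncation = c("none", "resample", "clip"),
                       total_mode = c("comonotonic", "independent")) {
  truncation <- match.arg(truncation)
  total_mode <- match.arg(total_mode)
  if (!is.numeric(iterations) || length(iterations) != 1 || iterations < 1) {
    stop("iterations must be a positive count", call. = FALSE)
  }
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop("confidence must lie in (0, 1)", call. = FALSE)
  }
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 confidence = confidence, truncation = truncation,
                 total_mode = total_mode),
            class = "sim_config")
}

#' Simulate the risk distribution of one behavior class
#'
#' Runs the per-iteration chain: factor draws -> F -> P = p_raw * F ->
#' hazard draw I -> risk R = P * I.
#'
#' @param p_raw Raw occurrence probability P' of the behavior, in \[0, 1\].
#' @param profile The working type's [factor_profile()].
#' @param spec The cell's [hazard_spec()].
#' @param cfg A [sim_config()].
#' @param coeffs A [model_coefficients()] object.
#' @return Numeric vector of `cfg$iterations` risk samples.
#' @examples
#' prof <- factor_profile("ventilation",
#'   list(a = c(0, 1), b = c(0, 1), c = c(3, 10), d = c(3, 10),
#'        e = c(0, 1), f = c(3, 10), g = c(1, 3), h = c(0, 1)))
#' spec <- hazard_spec("ventilation", "OIW", 2, 1.2)
#' r <- simulate_behavior_risk(0.16, prof, spec, sim_config(seed = 7))
#' mean(r)  # ~ 0.44
#' @export
simulate_behavior_risk <- function(p_raw, profile, spec, cfg = sim_config(),
                                   coeffs = model_coefficients()) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config", call. = FALSE)
  if (p_raw < 0 || p_raw > 1) stop("p_raw must lie in [0, 1]", call. = FALSE)
  n <- cfg$iterations
  withr::with_seed(cfg$seed, {
    fac <- sample_factors(profile, n)
    F <- .correction_factor_matrix(fac, coeffs)
    P <- revised_probability(p_raw, F)
    I <- .hazard_quantile(runif(n), spec$mean, spec$sd, cfg$truncation)
    P * I
  })
}

#' Simulate all behavior risks of a working type
#'
#' One seeded run over every behavior class of `working_type` that has a
#' positive count and a hazard spec in `study`. Factor draws are shared
#' across the behaviors within an iteration; hazard draws follow
#' `cfg$total_mode` (comonotonic: one shared uniform stream; independent:
#' one stream per behavior).
#'
#' @param study A [ub_study()] object.
#' @param working_type Working type id.
#' @param cfg A [sim_config()]; defaults to the study's settings.
#' @return An object of class `wt_risk`: list with the `samples` matrix
#'   (iterations x behaviors), the per-iteration `total`, the raw
#'   probabilities `p_raw` and the mode used.
#' @export
simulate_working_type <- function(study, working_type,
                                  cfg = study$simulation) {
  .check_tokens(working_type, .working_type_ids, "working type")
  cells <- study$hazard[study$hazard$working_type == working_type, ,
                        drop = FALSE]
  counts <- study$counts[study$counts$working_type == working_type &
                           study$counts$count > 0, , drop = FALSE]
  cells <- cells[match(counts$behavior, cells$behavior), , drop = FALSE]
  if (nrow(counts) == 0) {
    stop(sprintf("working type '%s' carries no behavior counts", working_type),
         call. = FALSE)
  }
  if (any(is.na(cells$mean))) {
    stop(sprintf("missing hazard spec for %s/%s", working_type,
                 paste(counts$behavior[is.na(cells$mean)], collapse = ",")),
         call. = FALSE)
  }
  p_raw <- setNames(counts$count / study$n_accidents, counts$behavior)
  profile <- study$profiles[[working_type]]
  n <- cfg$iterations
  withr::with_seed(cfg$seed, {
    fac <- sample_factors(profile, n)
    F <- .correction_factor_matrix(fac, study$coefficients)
    if (cfg$total_mode == "comonotonic") u_shared <- runif(n)
    samples <- matrix(vapply(seq_len(nrow(counts)), function(i) {
      u <- if (cfg$total_mode == "comonotonic") u_shared else runif(n)
      I <- .hazard_quantile(u, cells$mean[i], cells$sd[i], cfg$truncation)
      revised_probability(p_raw[i], F) * I
    }, numeric(n)), nrow = n)
    colnames(samples) <- counts$behavior
    structure(list(working_type = working_type,
                   samples = samples,
                   total = rowSums(samples),
                   p_raw = p_raw,
                   correction_factor_mean =
                     correction_factor_mean(profile, study$coefficients),
                   mode = cfg$total_mode),
              class = "wt_risk")
  })
}

#' @export
print.wt_risk <- function(x, ...) {
  cat(sprintf("Risk simulation for '%s' (%d iterations, %s totals)\n",
              x$working_type, nrow(x$samples), x$mode))
  m <- colMeans(x$samples)
  for (b in colnames(x$samples)) {
    cat(sprintf("  %-4s mean %.3e  sd %.3e\n", b, m[[b]], sd(x$samples[, b])))
  }
  cat(sprintf("  total mean %.3e  sd %.3e\n", mean(x$total), sd(x$total)))
  invisible(x)
}

#' Total risk across behavior classes
#'
#' Sums per-behavior risk sequences into a working-type total and
#' summarizes it. Under `"comonotonic"` coupling the sequences are
#' rank-aligned (each sorted) before summation — the coupling that
#' maximizes the variance of the sum and makes the total SD approximately
#' the sum of the component SDs; `"independent"` sums the sequences as
#' given.
#'
#' @param samples A named list of equal-length numeric vectors, or a matrix
#'   with one column per behavior.
#' @param mode Coupling mode.
#' @param confidence Level for the reported percentile interval.
#' @return A [summarize_risk()] summary of the total.
#' @export
total_risk <- function(samples, mode = c("comonotonic", "independent"),
                       confidence = 0.95) {
  mode <- match.arg(mode)
  if (is.list(samples)) {
    lens <- lengths(samples)
    if (length(unique(lens)) > 1) {
      stop("risk sequences must all have the same length", call. = FALSE)
    }
    samples <- do.call(cbind, samples)
  }
  if (mode == "comonotonic") samples <- apply(samples, 2, sort)
  summarize_risk(rowSums(as.matrix(samples)), confidence = confidence)
}

#' Summarize a simulated risk distribution
#'
#' Arithmetic mean and SD of the samples (the reporting convention for the
#' lognormal-looking outputs: sample moments, not log-space parameters), a
#' five-number quantile summary, the central percentile interval at
#' `confidence`, and the best-fitting distribution family when at least 50
#' samples are available.
#'
#' @param samples Numeric vector of at least 2 risk samples.
#' @param confidence Level of the central percentile interval.
#' @return An object of class `risk_summary` with fields `mean`, `sd`,
#'   `quantiles` (min/25%/50%/75%/max), `interval`, `fit_family`,
#'   `fit_params` and `n`.
#' @export
summarize_risk <- function(samples, confidence = 0.95) {
  if (length(samples) < 2) {
    stop("at least 2 samples are required to summarize a risk distribution",
         call. = FALSE)
  }
  qs <- quantile(samples, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  names(qs) <- c("min", "q25", "q50", "q75", "max")
  alpha <- (1 - confidence) / 2
  ci <- quantile(samples, c(alpha, 1 - alpha), names = FALSE)
  fit <- if (length(samples) >= 50 && sd(samples) > 0) {
    fit_distribution(samples)
  } else {
    list(family = NA_character_, params = NULL)
  }
  structure(list(mean = mean(samples), sd = sd(samples),
                 quantiles = as.list(qs),
                 interval = list(level = confidence, lower = ci[1],
                                 upper = ci[2]),
                 fit_family = fit$family,
                 fit_params = fit$params,
                 n = length(samples)),
            class = "risk_summary")
}

#' @export
print.risk_summary <- function(x, ...) {
  cat(sprintf("Risk summary (n = %d): mean %.3e, sd %.3e\n", x$n, x$mean, x$sd))
  cat(sprintf("  quantiles: min %.3e | q25 %.3e | median %.3e | q75 %.3e | max %.3e\n",
              x$quantiles$min, x$quantiles$q25, x$quantiles$q50,
              x$quantiles$q75, x$quantiles$max))
  cat(sprintf("  %g%% interval: [%.3e, %.3e]", 100 * x$interval$level,
              x$interval$lower, x$interval$upper))
  if (!is.na(x$fit_family)) cat(sprintf("  best fit: %s", x$fit_family))
  cat("\n")
  invisible(x)
}

# moment-matched CDFs of the candidate families
.fit_candidates <- function(m, s) {
  list(
    normal = list(params = list(mean = m, sd = s),
                  cdf = function(q) pnorm(q, m, s),
                  positive = FALSE),
    lognormal = local({
      sdlog <- sqrt(log1p((s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      list(params = list(meanlog = meanlog, sdlog = sdlog),
           cdf = function(q) plnorm(q, meanlog, sdlog),
           positive = TRUE)
    }),
    triangular = local({
      h <- sqrt(6) * s  # symmetric triangular half-width from the SD
      list(params = list(lower = m - h, upper = m + h),
           cdf = function(q) ptri(q, m - h, m + h),
           positive = FALSE)
    }),
    uniform = local({
      h <- sqrt(3) * s
      list(params = list(min = m - h, max = m + h),
           cdf = function(q) punif(q, m - h, m + h),
           positive = FALSE)
    })
  )
}

#' Select the best-fitting distribution family
#'
#' Moment-matches each candidate family to the sample mean and SD and
#' returns the family minimizing the Kolmogorov-Smirnov statistic, the
#' selection criterion of goodness-of-fit screens in spreadsheet risk
#' tools. Positive-support families are skipped (with a note) when the
#' sample contains non-positive values.
#'
#' @param samples Numeric vector of at least 50 samples.
#' @param candidates Subset of `c("normal", "lognormal", "triangular",
#'   "uniform")`.
#' @return A list with `family`, its moment-matched `params`, the named
#'   vector of KS statistics `ks`, and `skipped` (families not evaluated).
#' @examples
#' fit_distribution(rlnorm(1000, -1, 0.5))$family
#' @export
fit_distribution <- function(samples,
                             candidates = c("normal", "lognormal",
                                            "triangular", "uniform")) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  if (length(samples) < 50) {
    stop("at least 50 samples are required for distribution fitting",
         call. = FALSE)
  }
  if (sd(samples) == 0) {
    stop("samples are constant; no distribution family is identifiable",
         call. = FALSE)
  }
  all_fits <- .fit_candidates(mean(samples), sd(samples))[candidates]
  skipped <- character(0)
  if (any(samples <= 0)) {
    pos <- vapply(all_fits, `[[`, logical(1), "positive")
    skipped <- names(all_fits)[pos]
    if (length(skipped)) {
      message("skipping positive-support families (non-positive samples): ",
              paste(skipped, collapse = ", "))
    }
    all_fits <- all_fits[!pos]
  }
  if (!length(all_fits)) {
    stop("no candidate family is compatible with the samples", call. = FALSE)
  }
  ks <- vapply(all_fits, function(f) {
    unname(suppressWarnings(ks.test(samples, f$cdf)$statistic))
  }, numeric(1))
  best <- names(ks)[which.min(ks)]
  list(family = best, params = all_fits[[best]]$params, ks = ks,
       skipped = skipped)
}
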
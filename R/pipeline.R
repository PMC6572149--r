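# End-to-end orchestration: tabulated occurrence echo -> probability
# correction -> Monte Carlo risk simulation per key working type ->
# summaries and totals -> pooled sensitivity -> serializable report.

.summary_to_list <- function(s) {
  list(mean = s$mean, sd = s$sd, quantiles = s$quantiles,
       interval = s$interval, fit_family = s$fit_family,
       fit_params = s$fit_params, n = s$n)
}

.degenerate_summary <- function(samples) {
  v <- samples[1]
  list(mean = v, sd = NA, quantiles = list(min = v, q25 = v, q50 = v,
                                           q75 = v, max = v),
       interval = NULL, fit_family = NA, fit_params = NULL, n = 1,
       degenerate = TRUE)
}

#' Run the full risk-assessment pipeline
#'
#' Executes every stage on a study: occurrence probabilities and shares,
#' mean correction factors and revised probabilities, a seeded Monte Carlo
#' risk simulation per key working type (behavior summaries plus total),
#' and — optionally — the pooled contribution-to-variance sensitivity
#' analysis. Per-stage seeds are derived deterministically from
#' `cfg$seed`, so two runs with the same configuration produce identical
#' reports (apart from the timestamp).
#'
#' @param study A [ub_study()] object.
#' @param cfg A [sim_config()]; defaults to the study's settings.
#' @param sensitivity Include the pooled sensitivity decomposition.
#' @param sensitivity_iterations Iterations for the pooled decomposition
#'   (see [sensitivity_pooled()]).
#' @return An object of class `run_report`.
#' @examples
#' \donttest{
#' fx <- study_fixture()
#' rep <- run_pipeline(fx$study, sim_config(seed = 1), sensitivity = FALSE)
#' risk_table(rep)
#' }
#' @export
run_pipeline <- function(study, cfg = study$simulation, sensitivity = TRUE,
                         sensitivity_iterations = 1e6) {
  wts <- intersect(.key_working_types,
                   unique(study$counts$working_type[study$counts$count > 0]))
  occurrence <- occurrence_report(study)

  wt_reports <- list()
  for (i in seq_along(wts)) {
    wt <- wts[i]
    wt_cfg <- cfg
    wt_cfg$seed <- cfg$seed + i
    sim <- tryCatch(simulate_working_type(study, wt, wt_cfg),
                    error = function(e) {
                      stop(sprintf("simulation stage failed for '%s': %s", wt,
                                   conditionMessage(e)), call. = FALSE)
                    })
    summarize1 <- function(x) {
      if (length(x) < 2) .degenerate_summary(x)
      else .summary_to_list(summarize_risk(x, cfg$confidence))
    }
    per_behavior <- lapply(seq_len(ncol(sim$samples)), function(j)
      summarize1(sim$samples[, j]))
    names(per_behavior) <- colnames(sim$samples)
    wt_reports[[wt]] <- list(per_behavior = per_behavior,
                             total = summarize1(sim$total))
  }

  sens <- NULL
  if (isTRUE(sensitivity)) {
    sres <- sensitivity_pooled(study, iterations = sensitivity_iterations,
                               seed = cfg$seed + length(wts) + 1)
    sens <- as.data.frame(unclass(sres), stringsAsFactors = FALSE)
  }

  structure(list(
    config = c(study_to_list(study)["study"],
               list(model = study_to_list(study)$model,
                    simulation = unclass(cfg),
                    sensitivity_iterations =
                      if (isTRUE(sensitivity)) sensitivity_iterations else NULL)),
    occurrence = occurrence,
    working_types = wt_reports,
    sensitivity = sens,
    provenance = list(package = "ubrisk",
                      version = as.character(packageVersion("ubrisk")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Unsafe-behavior risk report\n")
  for (wt in names(x$working_types)) {
    tot <- x$working_types[[wt]]$total
    cat(sprintf("  %-20s total risk %.3e", wt, tot$mean))
    if (!is.na(tot$sd %||% NA)) cat(sprintf(" +/- %.3e", tot$sd))
    cat("\n")
  }
  if (!is.null(x$sensitivity)) {
    top <- rank_sensitivities(structure(x$sensitivity,
             class = c("sensitivity_result", "data.frame")))[1, ]
    cat(sprintf("  dominant sensitivity input: %s (%+.2f%%)\n",
                top$input, top$contribution))
  }
  invisible(x)
}

#' Occurrence and correction summary table
#'
#' One row per populated (working type, behavior) cell: citation count, raw
#' occurrence probability, the working type's mean correction factor,
#' revised probability (full precision plus the conventional 2-decimal
#' rendering) and the working type's percentage share of accidents.
#'
#' @param study A [ub_study()] object.
#' @return A data frame shaped like the classic occurrence-probability
#'   table.
#' @export
occurrence_report <- function(study) {
  counts <- study$counts[study$counts$count > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    wt <- counts$working_type[i]
    p_raw <- counts$count[i] / study$n_accidents
    Fbar <- correction_factor_mean(study$profiles[[wt]], study$coefficients)
    p_rev <- revised_probability(p_raw, Fbar)
    data.frame(working_type = wt, behavior = counts$behavior[i],
               count = counts$count[i], probability = p_raw,
               correction_factor = Fbar, revised_probability = p_rev,
               revised_2dp = round(p_rev, 2),
               share_pct = 100 * sum(counts$count[counts$working_type == wt]) /
                 study$n_accidents,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Risk table of a pipeline report
#'
#' Flattens a [run_pipeline()] report into one row per (working type,
#' behavior) cell plus a `total` row per working type, mirroring the
#' classic risk-value table layout.
#'
#' @param report A `run_report`.
#' @return A data frame with columns `working_type`, `behavior`, `mean`,
#'   `sd`, `fit_family`.
#' @export
risk_table <- function(report) {
  rows <- list()
  for (wt in names(report$working_types)) {
    blk <- report$working_types[[wt]]
    for (b in names(blk$per_behavior)) {
      s <- blk$per_behavior[[b]]
      rows[[length(rows) + 1]] <- data.frame(
        working_type = wt, behavior = b, mean = s$mean,
        sd = if (is.null(s$sd)) NA_real_ else as.numeric(s$sd),
        fit_family = as.character(s$fit_family %||% NA),
        stringsAsFactors = FALSE)
    }
    s <- blk$total
    rows[[length(rows) + 1]] <- data.frame(
      working_type = wt, behavior = "total", mean = s$mean,
      sd = if (is.null(s$sd)) NA_real_ else as.numeric(s$sd),
      fit_family = as.character(s$fit_family %||% NA),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize and restore pipeline reports
#'
#' Reports are written as JSON with full numeric precision;
#' `write_report(read_report(path), path2)` is byte-stable.
#'
#' @param report A `run_report`.
#' @param path Path to a JSON file.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   the parsed report.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_recursive(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       always_decimal = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  class(rep) <- "run_report"
  rep
}

# strip S3 classes so jsonlite sees plain lists / data frames
unclass_recursive <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x)))
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, unclass_recursive))
  }
  x
}
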
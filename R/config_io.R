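# Study container and configuration I/O. A study bundles everything the
# pipeline needs: accident counts, per-working-type factor profiles,
# hazard-index specs, model coefficients and simulation settings. On disk
# it is a YAML (or JSON) document; validation enumerates every violation,
# each named with its config path, rather than stopping at the first.

#' Construct a study object
#'
#' @param n_accidents Number of sampled accidents behind the counts.
#' @param counts Data frame with columns `working_type`, `behavior`,
#'   `count`.
#' @param profiles Named list of [factor_profile()] objects, one per
#'   working type appearing in `counts`.
#' @param hazard Data frame with columns `working_type`, `behavior`,
#'   `mean`, `sd`: the hazard-index spec of each populated cell.
#' @param coefficients A [model_coefficients()] object.
#' @param simulation A [sim_config()] object.
#' @return An object of class `ub_study`.
#' @export
ub_study <- function(n_accidents, counts, profiles, hazard,
                     coefficients = model_coefficients(),
                     simulation = sim_config()) {
  .check_tokens(as.character(counts$working_type), .working_type_ids,
                "working type")
  .check_tokens(as.character(counts$behavior), .behavior_codes,
                "behavior code")
  wts <- unique(counts$working_type[counts$count > 0])
  missing_prof <- setdiff(wts, names(profiles))
  if (length(missing_prof)) {
    stop("missing factor profile(s) for: ", paste(missing_prof, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(counts$working_type, counts$behavior)[counts$count > 0]
  hkey <- paste(hazard$working_type, hazard$behavior)
  missing_hz <- setdiff(key, hkey)
  if (length(missing_hz)) {
    stop("missing hazard spec(s) for: ", paste(missing_hz, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_accidents = as.integer(n_accidents),
                 counts = counts, profiles = profiles, hazard = hazard,
                 coefficients = coefficients, simulation = simulation),
            class = "ub_study")
}

#' @export
print.ub_study <- function(x, ...) {
  cat(sprintf("Unsafe-behavior risk study: %d accidents, %d populated cells\n",
              x$n_accidents, sum(x$counts$count > 0)))
  for (wt in names(x$profiles)) {
    k <- x$counts$working_type == wt & x$counts$count > 0
    cat(sprintf("  %-20s %2d behaviors, %3d citations\n", wt, sum(k),
                sum(x$counts$count[k])))
  }
  invisible(x)
}

#' Read a study configuration
#'
#' Parses a YAML or JSON study configuration, validates it (reporting
#' *all* violations, each named by its config path) and applies defaults
#' for absent model coefficients and simulation settings.
#'
#' The schema: `study.n_accidents`; `model.org_weights`, `model.slope`,
#' `model.intercept`; `simulation.iterations`, `.seed`, `.confidence`,
#' `.truncation`, `.total_mode`; and per working type
#' `working_types.<id>.factors.<a..h>` as `[lower, upper]` or
#' `[lower, mode, upper]`, plus
#' `working_types.<id>.behaviors.<CODE>.count` and `.hazard.mean` /
#' `.hazard.sd`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [ub_study()].
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  study_from_list(raw)
}

#' @rdname read_study_config
#' @param config A nested list following the configuration schema.
#' @export
study_from_list <- function(config) {
  errs <- character(0)
  note <- function(...) errs <<- c(errs, sprintf(...))

  n_acc <- config$study$n_accidents
  if (is.null(n_acc) || !is.numeric(n_acc) || n_acc < 1) {
    note("study.n_accidents: must be a positive count")
    n_acc <- NA_integer_
  }

  coeffs <- tryCatch(
    model_coefficients(
      org_weights = config$model$org_weights %||% c(0.2, 0.6, 0.2),
      slope = config$model$slope %||% 0.0167,
      intercept = config$model$intercept %||% 1.5),
    error = function(e) { note("model: %s", conditionMessage(e)); NULL })

  simc <- tryCatch(
    do.call(sim_config, config$simulation %||% list()),
    error = function(e) { note("simulation: %s", conditionMessage(e)); NULL })

  counts <- list(); profiles <- list(); hazard <- list()
  wts <- config$working_types
  if (is.null(wts) || !length(wts)) note("working_types: none defined")
  for (id in names(wts)) {
    if (!id %in% .working_type_ids) {
      note("working_types.%s: unknown working type id", id)
      next
    }
    block <- wts[[id]]
    prof <- tryCatch(factor_profile(id, block$factors %||% list()),
                     error = function(e) {
                       note("working_types.%s.%s", id, conditionMessage(e))
                       NULL
                     })
    if (!is.null(prof)) profiles[[id]] <- prof
    for (code in names(block$behaviors)) {
      cell <- block$behaviors[[code]]
      pathc <- sprintf("working_types.%s.behaviors.%s", id, code)
      if (!code %in% .behavior_codes) {
        note("%s: unknown behavior code", pathc)
        next
      }
      cnt <- cell$count
      if (is.null(cnt) || !is.numeric(cnt) || cnt < 0) {
        note("%s.count: must be a non-negative count", pathc)
        next
      }
      counts[[length(counts) + 1]] <-
        data.frame(working_type = id, behavior = code,
                   count = as.integer(cnt), stringsAsFactors = FALSE)
      hz <- cell$hazard
      if (is.null(hz)) {
        if (cnt > 0) note("%s.hazard: required for a populated cell", pathc)
        next
      }
      if (is.null(hz$mean) || !is.numeric(hz$mean) || hz$mean <= 0) {
        note("%s.hazard.mean: must be positive", pathc)
      } else if (is.null(hz$sd) || !is.numeric(hz$sd) || hz$sd < 0) {
        note("%s.hazard.sd: must be non-negative", pathc)
      } else {
        hazard[[length(hazard) + 1]] <-
          data.frame(working_type = id, behavior = code,
                     mean = hz$mean, sd = hz$sd, stringsAsFactors = FALSE)
      }
    }
  }

  if (length(errs)) {
    stop("invalid study configuration:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  ub_study(n_accidents = n_acc,
           counts = do.call(rbind, counts),
           profiles = profiles,
           hazard = do.call(rbind, hazard),
           coefficients = coeffs,
           simulation = simc)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# study -> plain nested list following the config schema
study_to_list <- function(study) {
  wt_blocks <- list()
  for (id in names(study$profiles)) {
    prof <- study$profiles[[id]]
    factors <- lapply(seq_len(nrow(prof)), function(i) {
      if (prof$mode[i] == (prof$lower[i] + prof$upper[i]) / 2) {
        c(prof$lower[i], prof$upper[i])
      } else {
        c(prof$lower[i], prof$mode[i], prof$upper[i])
      }
    })
    names(factors) <- prof$factor
    k <- study$counts$working_type == id
    behaviors <- list()
    for (j in which(k)) {
      code <- study$counts$behavior[j]
      hz <- study$hazard[study$hazard$working_type == id &
                           study$hazard$behavior == code, ]
      cell <- list(count = study$counts$count[j])
      if (nrow(hz)) cell$hazard <- list(mean = hz$mean[1], sd = hz$sd[1])
      behaviors[[code]] <- cell
    }
    wt_blocks[[id]] <- list(factors = factors, behaviors = behaviors)
  }
  list(study = list(n_accidents = study$n_accidents),
       model = list(org_weights = study$coefficients$org_weights,
                    slope = study$coefficients$slope,
                    intercept = study$coefficients$intercept),
       simulation = unclass(study$simulation),
       working_types = wt_blocks)
}

#' Write a study configuration
#'
#' Serializes a study to YAML (default) or JSON, chosen by the file
#' extension. Reading the file back yields an equivalent study.
#'
#' @param study A [ub_study()].
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(study, path) {
  cfg <- study_to_list(study)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
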
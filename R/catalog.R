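# Domain vocabulary: working types of underground coal mining and the 13
# unsafe-behavior classes of GB 6441-86 (Appendix A), plus tabulation of
# coded accident records into occurrence probabilities.

.behavior_codes <- c("OIW", "FSD", "UUD", "HIT", "ISO", "VDP", "CSU",
                     "WSI", "RIW", "WHD", "PPE", "UA", "MFE")

.behavior_descriptions <- c(
  OIW = "Operating incorrectly, ignoring safety and warning",
  FSD = "Failure of safety device",
  UUD = "Use of unsafe devices",
  HIT = "Hand instead of tool operation",
  ISO = "Improper storage of objects",
  VDP = "Venture into dangerous places",
  CSU = "Climbing and sitting in unsafe positions",
  WSI = "Work and stay under lifting objects",
  RIW = "Repair, inspection, welding, cleaning and other operations carried out while the machine is running",
  WHD = "Workers have distracted behaviors",
  PPE = "Neglected use of personal protective equipment where it must be used",
  UA  = "Unsafe attire",
  MFE = "Mishandling of flammable and explosive dangerous goods"
)

.working_type_ids <- c("ventilation", "gas_prevention_fire", "blasting",
                       "electrician", "mining", "transport")

.working_type_names <- c(
  ventilation         = "Ventilation",
  gas_prevention_fire = "Gas prevention and fire extinguishing",
  blasting            = "Blasting",
  electrician         = "Electrician",
  mining              = "Mining",
  transport           = "Transport"
)

.key_working_types <- c("ventilation", "gas_prevention_fire", "blasting",
                        "electrician")

#' Unsafe-behavior classes of GB 6441-86
#'
#' The 13 classes of unsafe worker behavior stipulated in Appendix A of the
#' Chinese accident-classification standard GB 6441-86. The three-letter
#' codes are immutable identifiers used throughout the package; behavior
#' columns in accident tables must use them.
#'
#' @return A data frame with columns `code` and `description`, one row per
#'   class (13 rows).
#' @examples
#' behavior_classes()
#' @export
behavior_classes <- function() {
  data.frame(code = .behavior_codes,
             description = unname(.behavior_descriptions[.behavior_codes]),
             stringsAsFactors = FALSE)
}

#' Working types associated with gas-explosion accidents
#'
#' Six occupational role categories of underground coal mining. Four of them
#' (ventilation, gas prevention and fire extinguishing, blasting,
#' electrician) are flagged as *key* working types: the roles with a high
#' frequency of gas-explosion involvement that the risk assessment targets.
#' Mining and transport are part of the vocabulary but typically carry no
#' behavior data.
#'
#' @return A data frame with columns `id` (text key used in accident tables
#'   and configurations), `name`, and `is_key` (logical).
#' @examples
#' subset(working_types(), is_key)
#' @export
working_types <- function() {
  data.frame(id = .working_type_ids,
             name = unname(.working_type_names[.working_type_ids]),
             is_key = .working_type_ids %in% .key_working_types,
             stringsAsFactors = FALSE)
}

.check_tokens <- function(tokens, known, what) {
  bad <- which(!(tokens %in% known))
  if (length(bad)) {
    stop(sprintf("unknown %s '%s' in row %d", what, tokens[bad[1]], bad[1]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Tabulate coded accident records into an occurrence table
#'
#' Aggregates accident citations — (working type, behavior class) pairs — into
#' counts per cell. Each row of `records` is one citation; an accident may in
#' principle contribute several citations, and `n_accidents` counts distinct
#' accident identifiers, not rows.
#'
#' @param records A data frame with character columns `accident_id`,
#'   `working_type` and `behavior_code`. Extra columns (e.g. `date`) are
#'   ignored. Unknown working types or behavior codes are rejected, naming
#'   the offending token and row.
#' @return An object of class `occurrence_table`: a list with `n_accidents`
#'   and `counts`, the latter a data frame over the full
#'   working type x behavior grid with a non-negative integer `count`.
#' @seealso [occurrence_probability()], [working_type_share()],
#'   [generate_accident_records()]
#' @examples
#' recs <- data.frame(accident_id = c("A1", "A2"),
#'                    working_type = c("ventilation", "blasting"),
#'                    behavior_code = c("OIW", "UUD"))
#' tab <- tabulate_occurrences(recs)
#' occurrence_probability(tab, "ventilation", "OIW")
#' @export
tabulate_occurrences <- function(records) {
  needed <- c("accident_id", "working_type", "behavior_code")
  if (!all(needed %in% names(records))) {
    stop("records must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  wt <- as.character(records$working_type)
  bc <- as.character(records$behavior_code)
  .check_tokens(wt, .working_type_ids, "working type")
  .check_tokens(bc, .behavior_codes, "behavior code")

  grid <- expand.grid(working_type = .working_type_ids,
                      behavior = .behavior_codes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- table(factor(wt, levels = .working_type_ids),
               factor(bc, levels = .behavior_codes))
  grid$count <- as.integer(tab[cbind(grid$working_type, grid$behavior)])
  grid <- grid[order(match(grid$working_type, .working_type_ids),
                     match(grid$behavior, .behavior_codes)), ]
  rownames(grid) <- NULL

  structure(list(n_accidents = length(unique(records$accident_id)),
                 counts = grid),
            class = "occurrence_table")
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("Occurrence table:", x$n_accidents, "accidents\n")
  nz <- x$counts[x$counts$count > 0, ]
  if (nrow(nz)) {
    totals <- tapply(nz$count, nz$working_type, sum)
    for (wt in names(totals)[!is.na(totals)]) {
      cat(sprintf("  %-20s %3d citations\n", wt, totals[[wt]]))
    }
  } else {
    cat("  (no citations)\n")
  }
  invisible(x)
}

#' @export
as.data.frame.occurrence_table <- function(x, ...) x$counts

.cell_count <- function(table, wt, bc) {
  .check_tokens(wt, .working_type_ids, "working type")
  .check_tokens(bc, .behavior_codes, "behavior code")
  i <- table$counts$working_type == wt & table$counts$behavior == bc
  sum(table$counts$count[i])
}

#' Raw occurrence probability of a behavior class
#'
#' The raw (uncorrected) probability P' of a behavior class for a working
#' type: its citation count divided by the number of sampled accidents.
#'
#' @param table An [occurrence_table][tabulate_occurrences()].
#' @param wt Working type id.
#' @param bc Behavior class code.
#' @return A probability in \[0, 1\].
#' @export
occurrence_probability <- function(table, wt, bc) {
  if (table$n_accidents <= 0) {
    stop("undefined probability: occurrence table has no accidents",
         call. = FALSE)
  }
  .cell_count(table, wt, bc) / table$n_accidents
}

#' Share of unsafe behaviors attributed to a working type
#'
#' Percentage of all sampled accidents whose citations fall under `wt`.
#' When every accident is coded to exactly one key working type, the shares
#' of the key types partition 100%.
#'
#' @inheritParams occurrence_probability
#' @return A percentage (0-100 scale).
#' @export
working_type_share <- function(table, wt) {
  if (table$n_accidents <= 0) {
    stop("undefined share: occurrence table has no accidents", call. = FALSE)
  }
  .check_tokens(wt, .working_type_ids, "working type")
  i <- table$counts$working_type == wt
  100 * sum(table$counts$count[i]) / table$n_accidents
}

#' Read or write a coded accident table
#'
#' The on-disk interchange format is a UTF-8 CSV with header
#' `accident_id,working_type,behavior_code` (plus an optional `date` column,
#' written empty), one citation per row. Working types use the ids of
#' [working_types()].
#'
#' @param path Path to a CSV file.
#' @return `read_accident_records()` returns the records data frame;
#'   `write_accident_records()` returns `path` invisibly.
#' @export
read_accident_records <- function(path) {
  recs <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  needed <- c("accident_id", "working_type", "behavior_code")
  if (!all(needed %in% names(recs))) {
    stop("accident CSV must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  recs
}

#' @rdname read_accident_records
#' @param records A data frame of accident citations.
#' @export
write_accident_records <- function(records, path) {
  out <- records[, c("accident_id", "working_type", "behavior_code")]
  out$date <- if ("date" %in% names(records)) records$date else ""
  write.csv(out, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
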
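#' Drop encounter-only procedure records
#'
#' Removes procedure codes that merely record that an encounter took
#' place (evaluation-and-management visit codes and the like) and carry
#' no information about diagnostics or treatment. With an empty exclusion
#' list this is the identity transform.
#'
#' @param events events table with a `code` column.
#' @param exclusion_codes character vector of codes to drop (default: the
#'   bundled E&M list, [em_exclusions()]).
#' @return the events with excluded codes removed.
#' @export
filter_informative_procedures <- function(events,
                                          exclusion_codes = em_exclusions()$code) {
  events[!events$code %in% exclusion_codes, , drop = FALSE]
}

#' Procedure category table by age group
#'
#' Aggregates in-window procedure events into high-level categories and
#' counts UNIQUE patients per category per age group (a patient with two
#' radiography events counts once in radiography: unique
#' patient-procedure pairs at category level). Categories reaching fewer
#' than `min_count` patients OR less than `min_pct` percent of the
#' stratum are flagged suppressed. Unmapped codes fall into an
#' `"uncategorized"` bucket with a warning.
#'
#' @param windowed_procedures in-window procedure events (after
#'   [filter_informative_procedures()]).
#' @param cohort output of [apply_exclusions()] (for age groups and
#'   stratum sizes).
#' @param mapping data.frame `code`, `category` (default the bundled
#'   fixture [procedure_categories()]).
#' @param min_count,min_pct suppression thresholds (defaults 20 patients
#'   and 1.0 percent of the stratum).
#' @return data.frame `category`, `age_group`, `n_patients`, `percent`,
#'   `suppressed`; attribute `stratum_n`.
#' @export
categorize_procedures <- function(windowed_procedures, cohort,
                                  mapping = procedure_categories(),
                                  min_count = 20, min_pct = 1.0) {
  inc <- included(cohort)
  ev <- as.data.table(windowed_procedures)
  if ("event_class" %in% names(ev)) ev <- ev[event_class == "procedure"]
  ev[, category := mapping$category[match(code, mapping$code)]]
  if (anyNA(ev$category)) {
    warning(sprintf("%d unmapped procedure code(s) counted as 'uncategorized'",
                    length(unique(ev$code[is.na(ev$category)]))))
    ev[is.na(category), category := "uncategorized"]
  }
  ev <- merge(ev, as.data.table(inc[, c("person_id", "age_group")]),
              by = "person_id")
  counts <- unique(ev[, .(person_id, category, age_group)])[
    , .(n_patients = .N), by = .(category, age_group)]
  groups <- age_bins()$labels
  stratum_n <- setNames(vapply(groups, function(g) sum(inc$age_group == g),
                               numeric(1)), groups)
  grid <- CJ(category = sort(unique(counts$category)), age_group = groups)
  counts <- merge(grid, counts, by = c("category", "age_group"), all.x = TRUE)
  counts[is.na(n_patients), n_patients := 0]
  out <- as.data.frame(counts)
  out$percent <- pct(out$n_patients, stratum_n[out$age_group])
  out$suppressed <- out$n_patients < min_count |
    (!is.na(out$percent) & out$percent < min_pct)
  attr(out, "stratum_n") <- stratum_n
  out
}

#' Newly started medications in the analysis window
#'
#' Keeps, per patient, drug ingredients with at least one record inside
#' the closed window `[index, index + window_days]` and NO record at any
#' time before the index date (full lookback): long-standing
#' prescriptions carried into the window are excluded so the result
#' reflects drugs newly started around the diagnosis. Extending the
#' lookback can only remove drugs, never add them.
#'
#' @param drug_events drug events with `person_id`, `code` (ingredient),
#'   `date`; rows with `event_class != "drug"` are ignored when the
#'   column is present.
#' @param index data.frame `person_id`, `index_date` (from
#'   [derive_index()] or a cohort).
#' @param window_days window length (default 60).
#' @return data.frame of in-window events for qualifying
#'   (patient, ingredient) pairs, with an `index_date` column.
#' @export
new_medications <- function(drug_events, index, window_days = 60) {
  ev <- as.data.table(drug_events)
  if ("event_class" %in% names(ev)) ev <- ev[event_class == "drug"]
  if (nrow(ev) == 0) return(as.data.frame(ev))
  ev[, date := parse_date(date, "drug event date")]
  idx <- as.data.table(index)[, .(person_id, index_date)]
  idx[, index_date := parse_date(index_date, "index date")]
  ev <- merge(ev, idx, by = "person_id")
  prior <- unique(ev[date < index_date, .(person_id, code)])
  inwin <- ev[date >= index_date & date <= index_date + window_days]
  out <- inwin[!prior, on = c("person_id", "code")]
  as.data.frame(out)
}

#' ATC level-3 rollup of new-medication events
#'
#' Maps ingredients to 7-character ATC codes and truncates to the
#' level-3 pharmacological subgroup — the first four characters (one
#' letter, two digits, one letter; e.g. `J01CA04` -> `J01C`) — then
#' counts unique patients per class per age group. Unmapped ingredients
#' fall into an `"unmapped"` bucket with a warning.
#'
#' @param new_drug_events output of [new_medications()].
#' @param cohort output of [apply_exclusions()].
#' @param atc_map data.frame `ingredient`, `atc7` (default the bundled
#'   fixture [atc_ingredients()]).
#' @return data.frame `atc3`, `age_group`, `n_patients`, `percent`;
#'   attribute `stratum_n`.
#' @export
atc_rollup <- function(new_drug_events, cohort, atc_map = atc_ingredients()) {
  inc <- included(cohort)
  groups <- age_bins()$labels
  stratum_n <- setNames(vapply(groups, function(g) sum(inc$age_group == g),
                               numeric(1)), groups)
  ev <- as.data.table(new_drug_events)
  if (nrow(ev) == 0) {
    out <- data.frame(atc3 = character(0), age_group = character(0),
                      n_patients = numeric(0), percent = numeric(0))
    attr(out, "stratum_n") <- stratum_n
    return(out)
  }
  ev[, atc3 := substr(atc_map$atc7[match(code, atc_map$ingredient)], 1, 4)]
  if (anyNA(ev$atc3)) {
    warning(sprintf("%d unmapped ingredient(s) counted as 'unmapped'",
                    length(unique(ev$code[is.na(ev$atc3)]))))
    ev[is.na(atc3), atc3 := "unmapped"]
  }
  ev <- merge(ev, as.data.table(inc[, c("person_id", "age_group")]),
              by = "person_id")
  counts <- unique(ev[, .(person_id, atc3, age_group)])[
    , .(n_patients = .N), by = .(atc3, age_group)]
  setorder(counts, atc3, age_group)
  out <- as.data.frame(counts)
  out$percent <- pct(out$n_patients, stratum_n[out$age_group])
  attr(out, "stratum_n") <- stratum_n
  out
}

#' Monthly code-uptake series
#'
#' Unique patients using each tracked code per calendar month over a date
#' range (by default the index code and its pre-release placeholder).
#' The series is NOT restricted to any cohort window; it spans the full
#' lookback so the hand-off from the placeholder code to the new code
#' around the release date is visible. Months are contiguous and
#' zero-filled.
#'
#' @param events coded-events table (`person_id`, `code`, `date`).
#' @param codes codes to track (default `c("U09.9", "B94.8")`).
#' @param date_range length-2 Date (or ISO string) vector, closed range.
#' @return data.frame `month` (first of month, Date), `code`,
#'   `n_patients`.
#' @export
uptake_series <- function(events, codes = c("U09.9", "B94.8"),
                          date_range = as.Date(c("2018-01-01", "2022-05-31"))) {
  date_range <- parse_date(date_range, "date range")
  if (length(date_range) != 2 || date_range[1] > date_range[2]) {
    stop("date_range must be two dates with start <= end", call. = FALSE)
  }
  months <- seq(as.Date(format(date_range[1], "%Y-%m-01")),
                as.Date(format(date_range[2], "%Y-%m-01")), by = "month")
  ev <- as.data.table(events)[code %in% codes]
  grid <- CJ(month = months, code = codes)
  if (nrow(ev) == 0) {
    out <- as.data.frame(grid)
    out$n_patients <- 0
    return(out)
  }
  ev[, date := parse_date(date, "event date")]
  ev <- ev[date >= date_range[1] & date <= date_range[2]]
  ev[, month := as.Date(format(date, "%Y-%m-01"))]
  counts <- unique(ev[, .(person_id, code, month)])[
    , .(n_patients = .N), by = .(month, code)]
  out <- merge(grid, counts, by = c("month", "code"), all.x = TRUE)
  out[is.na(n_patients), n_patients := 0]
  setorder(out, code, month)
  as.data.frame(out)
}
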
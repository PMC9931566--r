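#' Index-date rule
#'
#' The index date is the earliest qualifying code date inside the closed
#' calendar window. Codes dated before the window start never define an
#' index: the code was only released at the window start, so earlier
#' occurrences are retroactive annotations (e.g. problem-list onset
#' dates) whose timing cannot be trusted.
#'
#' @param code qualifying diagnosis code (default `"U09.9"`).
#' @param window_start,window_end closed calendar interval in which a code
#'   occurrence can define an index date.
#' @param window_days length of the post-index analysis window (default 60
#'   days; the window is closed on both ends).
#' @return an `index_rule` object.
#' @export
index_rule <- function(code = "U09.9",
                       window_start = as.Date("2021-10-01"),
                       window_end = as.Date("2022-05-26"),
                       window_days = 60) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (window_start > window_end) {
    stop("index_rule: window_start must be <= window_end", call. = FALSE)
  }
  if (window_days < 0) stop("index_rule: window_days must be >= 0", call. = FALSE)
  structure(list(code = code, window_start = window_start,
                 window_end = window_end, window_days = window_days),
            class = "index_rule")
}

#' Derive per-person index dates
#'
#' @param events data.frame of coded events with columns `person_id`,
#'   `code`, `date` (ISO strings or Dates).
#' @param rule an [index_rule()].
#' @return data.frame `person_id`, `index_date` (Date), one row per person
#'   with at least one qualifying in-window code; persons with no
#'   qualifying code are absent.
#' @export
derive_index <- function(events, rule = index_rule()) {
  ev <- as.data.table(events)[code == rule$code]
  if (nrow(ev) == 0) {
    return(data.frame(person_id = character(0),
                      index_date = as.Date(character(0))))
  }
  ev[, date := parse_date(date, "event date")]
  ev <- ev[date >= rule$window_start & date <= rule$window_end]
  idx <- ev[, .(index_date = min(date)), by = person_id]
  setkey(idx, person_id)
  as.data.frame(idx)
}

#' Site-quality criteria
#'
#' Minimum data-quality gates a contributing site must meet: at least
#' `min_lab_coverage` of inpatients with core labs recorded (white blood
#' cell count and serum creatinine), at least `min_valid_end_dates` of
#' inpatient visits with valid end dates, dates shifted by at most
#' `max_date_shift_days`, and nonzero use of the index code. Coverage
#' thresholds are inclusive (a site at exactly the threshold passes); the
#' shift threshold is inclusive on the allowed side (exactly 30 days
#' passes, 31 fails).
#'
#' @param min_lab_coverage minimum lab-coverage fraction (default 0.25).
#' @param min_valid_end_dates minimum valid inpatient end-date fraction
#'   (default 0.75).
#' @param max_date_shift_days maximum tolerated site date shift in days
#'   (default 30).
#' @return a `site_criteria` object.
#' @export
site_criteria <- function(min_lab_coverage = 0.25,
                          min_valid_end_dates = 0.75,
                          max_date_shift_days = 30) {
  for (f in c(min_lab_coverage, min_valid_end_dates)) {
    if (f < 0 || f > 1) {
      stop("site_criteria: coverage fractions must lie in [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(min_lab_coverage = min_lab_coverage,
                 min_valid_end_dates = min_valid_end_dates,
                 max_date_shift_days = max_date_shift_days),
            class = "site_criteria")
}

#' Filter sites by data-quality criteria
#'
#' @param site_metadata data.frame with columns `site_id`, `lab_coverage`,
#'   `valid_end_frac`, `date_shift_days`, `index_code_use`.
#' @param criteria a [site_criteria()].
#' @return character vector of eligible site ids.
#' @export
filter_sites <- function(site_metadata, criteria = site_criteria()) {
  need <- c("site_id", "lab_coverage", "valid_end_frac", "date_shift_days",
            "index_code_use")
  miss <- setdiff(need, names(site_metadata))
  if (length(miss) > 0) {
    stop(sprintf("site_metadata: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  keep <- site_metadata$lab_coverage >= criteria$min_lab_coverage &
    site_metadata$valid_end_frac >= criteria$min_valid_end_dates &
    site_metadata$date_shift_days <= criteria$max_date_shift_days &
    site_metadata$index_code_use > 0
  site_metadata$site_id[keep]
}

#' Assign age groups at a reference date
#'
#' Bins are `[0,21)`, `[21,46)`, `[46,66)`, `[66,Inf)`, labelled
#' `<21`, `21-45`, `46-65`, `66+`. Age is completed years at `at`.
#'
#' @param birth_date Date vector (or ISO strings).
#' @param at reference Date vector (recycled).
#' @return character vector of age-group labels.
#' @export
assign_age_group <- function(birth_date, at) {
  birth_date <- parse_date(birth_date, "birth date")
  at <- parse_date(at, "reference date")
  age <- floor(as.numeric(at - birth_date) / 365.25)
  bins <- age_bins()
  cut(age, breaks = c(bins$lower, Inf), labels = bins$labels,
      right = FALSE) |> as.character()
}

#' Apply cohort exclusions
#'
#' Starting from all indexed persons, excludes (1) deceased persons and
#' (2) persons whose index date falls inside (closed interval) any
#' inpatient visit — co-occurring features during a hospitalization cannot
#' be separated from the admission's primary cause. Every indexed person
#' appears exactly once, with an empty `exclusion_reason` if included.
#'
#' @param persons persons table (needs `person_id`, `birth_date`,
#'   `deceased`; flag columns `hospitalized_acute`, `severe_acute`,
#'   `covid_index_available` are carried through when present).
#' @param visits visits table (`person_id`, `start_date`, `end_date`,
#'   `inpatient`).
#' @param index output of [derive_index()].
#' @return data.frame (class `lc_cohort`): `person_id`, `index_date`,
#'   `age_group`, flag columns, `exclusion_reason` (`""`, `"deceased"` or
#'   `"inpatient_index"`).
#' @export
apply_exclusions <- function(persons, visits, index) {
  vis <- as.data.table(visits)
  if (nrow(vis) > 0) {
    vis[, start_date := parse_date(start_date, "visit start date")]
    vis[, end_date := parse_date(end_date, "visit end date")]
    bad <- which(!is.na(vis$end_date) & vis$end_date < vis$start_date)
    if (length(bad) > 0) {
      stop(sprintf("visit end before start at row(s) %s",
                   paste(head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  per <- as.data.table(persons)
  idx <- as.data.table(index)
  cohort <- merge(idx, per, by = "person_id")
  cohort[, age_group := assign_age_group(birth_date, index_date)]

  cohort[, exclusion_reason := ""]
  cohort[deceased == TRUE, exclusion_reason := "deceased"]

  if (nrow(vis) > 0) {
    inp <- vis[inpatient == TRUE]
    if (nrow(inp) > 0) {
      hits <- merge(cohort[, .(person_id, index_date)], inp, by = "person_id",
                    allow.cartesian = TRUE)
      hit_ids <- unique(hits[index_date >= start_date &
                               index_date <= end_date, person_id])
      cohort[person_id %in% hit_ids & exclusion_reason == "",
             exclusion_reason := "inpatient_index"]
    }
  }

  keep <- c("person_id", "index_date", "age_group",
            intersect(c("hospitalized_acute", "severe_acute",
                        "covid_index_available"), names(cohort)),
            "exclusion_reason")
  out <- as.data.frame(cohort[, ..keep])
  class(out) <- c("lc_cohort", "data.frame")
  out
}

#' Included subset of a cohort
#'
#' @param cohort output of [apply_exclusions()].
#' @return the rows with empty `exclusion_reason`.
#' @export
included <- function(cohort) {
  cohort[cohort$exclusion_reason == "", , drop = FALSE]
}

#' Restrict events to each person's analysis window
#'
#' Keeps events dated in the closed interval
#' `[index_date, index_date + window_days]` for included cohort members.
#' Events prior to index are dropped from the window set but are never
#' used to exclude a condition: a pre-existing condition recorded again
#' in-window is retained, since it may be exacerbated by (or newly
#' co-occur with) the indexed disease.
#'
#' @param cohort output of [apply_exclusions()].
#' @param events coded-events table.
#' @param window_days window length in days (default 60).
#' @return data.frame of in-window events with an `index_date` column.
#' @export
window_events <- function(cohort, events, window_days = 60) {
  inc <- included(cohort)
  ev <- as.data.table(events)
  ev[, date := parse_date(date, "event date")]
  idx <- as.data.table(inc[, c("person_id", "index_date")])
  ev <- merge(ev, idx, by = "person_id")
  out <- ev[date >= index_date & date <= index_date + window_days]
  as.data.frame(out)
}

#' Headline cohort summary
#'
#' Counts and one-decimal percentages for the attrition and acute-illness
#' profile of the cohort: initial indexed persons, exclusions by reason,
#' base population, acute hospitalization (and percent of base), severe
#' acute hospitalization (percent of base and of hospitalized), and
#' missing acute COVID index (percent of base). Percentages use half-up
#' rounding; an undefined percentage (zero denominator) is `NA`, never 0.
#'
#' @param cohort output of [apply_exclusions()] with flag columns.
#' @return named list (class `cohort_summary`).
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  inc <- included(cohort)
  n_initial <- nrow(cohort)
  n_deceased <- sum(cohort$exclusion_reason == "deceased")
  n_inpt <- sum(cohort$exclusion_reason == "inpatient_index")
  n_base <- nrow(inc)
  n_hosp <- sum(inc$hospitalized_acute, na.rm = TRUE)
  n_severe <- sum(inc$severe_acute, na.rm = TRUE)
  n_missing <- sum(!inc$covid_index_available, na.rm = TRUE)
  structure(list(
    n_initial = n_initial,
    n_excluded_deceased = n_deceased,
    n_excluded_inpatient_index = n_inpt,
    n_base = n_base,
    n_hospitalized_acute = n_hosp,
    pct_hospitalized_acute = pct(n_hosp, n_base),
    n_severe = n_severe,
    pct_severe_of_base = pct(n_severe, n_base),
    pct_severe_of_hospitalized = pct(n_severe, n_hosp),
    n_missing_covid_index = n_missing,
    pct_missing_covid_index = pct(n_missing, n_base)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  indexed persons:            %d\n", x$n_initial))
  cat(sprintf("  excluded, deceased:         %d\n", x$n_excluded_deceased))
  cat(sprintf("  excluded, inpatient index:  %d\n", x$n_excluded_inpatient_index))
  cat(sprintf("  base population:            %d\n", x$n_base))
  cat(sprintf("  hospitalized acute:         %d (%.1f%%)\n",
              x$n_hospitalized_acute, x$pct_hospitalized_acute))
  cat(sprintf("  severe acute:               %d (%.1f%% of base, %.1f%% of hospitalized)\n",
              x$n_severe, x$pct_severe_of_base, x$pct_severe_of_hospitalized))
  cat(sprintf("  missing COVID index:        %d (%.1f%%)\n",
              x$n_missing_covid_index, x$pct_missing_covid_index))
  invisible(x)
}
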
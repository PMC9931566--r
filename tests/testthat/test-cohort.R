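test_that("index derivation takes the earliest in-window code and ignores pre-window codes", {
  fx <- tiny_cohort_tables()
  idx <- derive_index(fx$events)
  # earliest of two qualifying dates
  expect_equal(idx$index_date[idx$person_id == "P1"], as.Date("2021-11-01"))
  # a code dated only before the release window defines no index
  # (it may have been retroactively applied)
  expect_false("P2" %in% idx$person_id)
})

test_that("the index window is closed at both ends", {
  ev <- data.frame(person_id = c("A", "B"), code = "U09.9",
                   date = c("2022-05-26", "2021-10-01"))
  idx <- derive_index(ev)
  expect_equal(idx$index_date[idx$person_id == "A"], as.Date("2022-05-26"))
  expect_equal(idx$index_date[idx$person_id == "B"], as.Date("2021-10-01"))
})

test_that("unparseable event dates fail with a row reference", {
  ev <- data.frame(person_id = "A", code = "U09.9", date = "not-a-date")
  expect_error(derive_index(ev), "row")
})

test_that("exclusions cover inpatient-overlapping index and deceased, with reasons", {
  fx <- tiny_cohort_tables()
  idx <- derive_index(fx$events)
  cohort <- apply_exclusions(fx$persons, fx$visits, idx)
  # P3's index 2022-01-10 falls inside the inpatient stay 01-05..01-15
  expect_equal(cohort$exclusion_reason[cohort$person_id == "P3"],
               "inpatient_index")
  expect_equal(cohort$exclusion_reason[cohort$person_id == "P4"], "deceased")
  expect_equal(cohort$exclusion_reason[cohort$person_id == "P1"], "")
  # partition property: every indexed person appears exactly once
  expect_setequal(cohort$person_id, idx$person_id)
  expect_equal(anyDuplicated(cohort$person_id), 0)
})

test_that("exclusion is idempotent: re-applying to the included set removes nobody", {
  fx <- tiny_cohort_tables()
  idx <- derive_index(fx$events)
  cohort <- apply_exclusions(fx$persons, fx$visits, idx)
  inc <- included(cohort)
  again <- apply_exclusions(fx$persons, fx$visits,
                            inc[, c("person_id", "index_date")])
  expect_equal(nrow(included(again)), nrow(inc))
})

test_that("a visit ending before it starts is rejected", {
  fx <- tiny_cohort_tables()
  bad <- data.frame(person_id = "P1", start_date = "2022-01-10",
                    end_date = "2022-01-05", inpatient = TRUE)
  idx <- derive_index(fx$events)
  expect_error(apply_exclusions(fx$persons, bad, idx), "row")
})

test_that("site filters use inclusive coverage thresholds and the 30-day shift bound", {
  meta <- data.frame(
    site_id = c("A", "B", "C", "D", "E"),
    lab_coverage = c(0.24, 0.25, 0.80, 0.80, 0.80),
    valid_end_frac = c(0.90, 0.75, 0.90, 0.74, 0.90),
    date_shift_days = c(0, 30, 31, 0, 0),
    index_code_use = c(10, 10, 10, 10, 0))
  keep <- filter_sites(meta)
  expect_equal(keep, "B")  # 0.25 and 0.75 exactly pass; 31-day shift fails;
                           # zero index-code use fails
  expect_error(filter_sites(meta[, -2]), "lab_coverage")
})

test_that("the analysis window is closed and prior events never exclude conditions", {
  persons <- data.frame(person_id = "P1", birth_date = "1980-01-01",
                        sex = "Female", race = "White",
                        ethnicity = "Not Hispanic/Latino", zip = "10001",
                        deceased = FALSE, site_id = "S01")
  idx <- data.frame(person_id = "P1", index_date = as.Date("2022-01-01"))
  cohort <- apply_exclusions(persons, data.frame(), idx)
  ev <- data.frame(person_id = "P1",
                   code = c("Fatigue", "Cough", "Fatigue", "Dyspnea"),
                   date = c("2021-12-02", "2022-01-11", "2022-03-02",
                            "2021-12-31"),
                   event_class = "condition")
  we <- window_events(cohort, ev, window_days = 60)
  # index-30 Fatigue is out of window, but the index+60 record is retained
  expect_setequal(we$code, c("Cough", "Fatigue"))
  expect_equal(we$date[we$code == "Fatigue"], as.Date("2022-03-02"))
})

test_that("windowed event count is non-decreasing in window length", {
  tabs <- generate_population(two_subtype_config(n = 300, seed = 6))
  cohort <- build_cohort(tabs)$cohort
  counts <- vapply(c(0, 15, 30, 60, 90), function(w) {
    nrow(window_events(cohort, tabs$coded_events, w))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("age-group assignment is total and disjoint over ages 0-120", {
  at <- as.Date("2022-01-01")
  births <- at - round(seq(0, 120, by = 0.5) * 365.25)
  groups <- assign_age_group(births, at)
  expect_false(anyNA(groups))
  expect_true(all(groups %in% c("<21", "21-45", "46-65", "66+")))
  # boundary ages land in the upper bin
  for (case in list(c(20, "<21"), c(21, "21-45"), c(45, "21-45"),
                    c(46, "46-65"), c(66, "66+"))) {
    b <- at - round(as.numeric(case[1]) * 365.25) - 1
    expect_equal(assign_age_group(b, at), case[2])
  }
})

test_that("cohort summary reports headline counts with one-decimal half-up percentages", {
  cohort <- data.frame(
    person_id = sprintf("P%d", 1:10),
    index_date = as.Date("2022-01-01"),
    age_group = "21-45",
    hospitalized_acute = c(rep(TRUE, 3), rep(FALSE, 7)),
    severe_acute = c(TRUE, rep(FALSE, 9)),
    covid_index_available = c(rep(TRUE, 6), rep(FALSE, 4)),
    exclusion_reason = c(rep("", 9), "inpatient_index"))
  s <- summarize_cohort(cohort)
  expect_equal(s$n_base, 9)
  expect_equal(s$pct_hospitalized_acute, round_half_up(100 * 3 / 9, 1))
  expect_equal(s$pct_severe_of_hospitalized, round_half_up(100 * 1 / 3, 1))
  # zero denominator reports NA, never 0
  cohort$hospitalized_acute <- FALSE
  cohort$severe_acute <- FALSE
  s0 <- summarize_cohort(cohort)
  expect_true(is.na(s0$pct_severe_of_hospitalized))
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(0.35, 1), 0.4)
  expect_equal(round_half_up(24.2192, 1), 24.2)
  expect_equal(pct(0, 0), NA_real_)
})
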
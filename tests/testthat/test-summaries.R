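test_that("encounter-only procedure codes are dropped and everything else retained", {
  ev <- data.frame(person_id = c("P1", "P1", "P2"),
                   code = c("99212", "93306", "97110"),
                   event_class = "procedure")
  out <- filter_informative_procedures(ev)
  expect_setequal(out$code, c("93306", "97110"))
  # an empty exclusion list is the identity transform
  expect_equal(filter_informative_procedures(ev, character(0)), ev)
})

test_that("procedure categories count unique patients and apply both suppression rules", {
  # stratum of 2500 patients, all 21-45
  n <- 2500
  cohort <- data.frame(person_id = sprintf("P%d", 1:n),
                       index_date = as.Date("2022-01-01"),
                       age_group = "21-45",
                       exclusion_reason = "")
  ev <- rbind(
    # one patient with two radiography events counts once
    data.frame(person_id = "P1", code = c("71046", "71250"),
               event_class = "procedure"),
    # 29 more radiography patients: 30 patients = 1.2% -> shown
    data.frame(person_id = sprintf("P%d", 2:30), code = "71046",
               event_class = "procedure"),
    # 19 echocardiography patients -> suppressed by the <20 rule
    data.frame(person_id = sprintf("P%d", 1:19), code = "93306",
               event_class = "procedure"),
    # 22 sleep-study patients = 0.9% -> suppressed by the <1.0% rule
    data.frame(person_id = sprintf("P%d", 1:22), code = "95810",
               event_class = "procedure"))
  tab <- categorize_procedures(ev, cohort)
  radio <- tab[tab$category == "radiography" & tab$age_group == "21-45", ]
  expect_equal(radio$n_patients, 30)
  expect_false(radio$suppressed)
  echo <- tab[tab$category == "echocardiography" & tab$age_group == "21-45", ]
  expect_true(echo$suppressed)
  sleep <- tab[tab$category == "sleep study" & tab$age_group == "21-45", ]
  expect_equal(sleep$percent, 0.9)
  expect_true(sleep$suppressed)
  # counts never exceed the stratum size
  expect_true(all(tab$n_patients <= n))
})

test_that("unmapped procedure codes fall into an uncategorized bucket with a warning", {
  cohort <- data.frame(person_id = "P1", index_date = as.Date("2022-01-01"),
                       age_group = "66+", exclusion_reason = "")
  ev <- data.frame(person_id = "P1", code = "00000",
                   event_class = "procedure")
  expect_warning(tab <- categorize_procedures(ev, cohort), "unmapped")
  expect_true("uncategorized" %in% tab$category)
})

test_that("new-medication selection keeps clean in-window starts only", {
  idx <- data.frame(person_id = "P1", index_date = as.Date("2022-01-01"))
  ev <- data.frame(
    person_id = "P1",
    code = c("sertraline", "sertraline",   # record 10 days before index
             "albuterol",                  # clean start at index+30
             "prednisone"),                # only at index+61: outside window
    date = c("2021-12-22", "2022-01-06", "2022-01-31", "2022-03-03"),
    event_class = "drug")
  out <- new_medications(ev, idx, window_days = 60)
  expect_equal(out$code, "albuterol")
})

test_that("extending the lookback never adds a new medication", {
  tabs <- generate_population(two_subtype_config(n = 400, seed = 44))
  idx <- derive_index(tabs$coded_events)
  full <- new_medications(tabs$coded_events, idx)
  # restrict to a 45-day lookback by shifting earlier records out
  ev <- tabs$coded_events
  ev <- ev[ev$event_class == "drug", ]
  ev$date <- as.Date(ev$date)
  idx_map <- setNames(idx$index_date, idx$person_id)
  keep <- ev$date >= idx_map[ev$person_id] - 45
  short <- new_medications(ev[keep, ], idx)
  full_keys <- paste(full$person_id, full$code)
  short_keys <- paste(short$person_id, short$code)
  expect_true(all(full_keys %in% short_keys))
})

test_that("ATC rollup truncates to level 3 and counts patients once per class", {
  cohort <- data.frame(person_id = c("P1", "P2"),
                       index_date = as.Date("2022-01-01"),
                       age_group = c("21-45", "21-45"),
                       exclusion_reason = "")
  ev <- data.frame(person_id = c("P1", "P1", "P2"),
                   code = c("amoxicillin", "amoxicillin", "doxycycline"),
                   date = "2022-01-10", event_class = "drug",
                   index_date = as.Date("2022-01-01"))
  tab <- atc_rollup(ev, cohort)
  # J01CA04 -> J01C; J01AA02 -> J01A
  expect_setequal(tab$atc3, c("J01C", "J01A"))
  expect_equal(tab$n_patients[tab$atc3 == "J01C"], 1)
  # empty input gives an empty table
  empty <- atc_rollup(ev[0, ], cohort)
  expect_equal(nrow(empty), 0)
  # unmapped ingredients are bucketed with a warning
  ev$code[3] <- "unobtainium"
  expect_warning(tab2 <- atc_rollup(ev, cohort), "unmapped")
  expect_true("unmapped" %in% tab2$atc3)
})

test_that("uptake series counts unique patients per month over a contiguous range", {
  ev <- data.frame(
    person_id = c("P1", "P1", "P2", "P3"),
    code = c("U09.9", "U09.9", "B94.8", "U09.9"),
    date = c("2021-11-03", "2021-11-20", "2021-03-15", "2021-12-01"))
  out <- uptake_series(ev, date_range = c("2021-01-01", "2021-12-31"))
  expect_equal(out$n_patients[out$code == "U09.9" &
                                out$month == as.Date("2021-11-01")], 1)
  expect_equal(out$n_patients[out$code == "B94.8" &
                                out$month == as.Date("2021-03-01")], 1)
  # contiguous months, zero-filled
  months <- sort(unique(out$month))
  expect_equal(months, seq(as.Date("2021-01-01"), as.Date("2021-12-01"),
                           by = "month"))
  expect_equal(sum(out$n_patients), 3)
  # absent codes give an all-zero series, not an error
  zero <- uptake_series(ev[0, ], date_range = c("2021-01-01", "2021-02-28"))
  expect_true(all(zero$n_patients == 0))
  expect_error(uptake_series(ev, date_range = c("2022-01-01", "2021-01-01")),
               "start <= end")
})

test_that("uptake totals match brute-force distinct patient-code-month triples", {
  tabs <- generate_population(two_subtype_config(n = 600, seed = 27))
  out <- uptake_series(tabs$coded_events,
                       date_range = c("2018-01-01", "2022-07-31"))
  ev <- tabs$coded_events[tabs$coded_events$code %in% c("U09.9", "B94.8"), ]
  triples <- unique(data.frame(p = ev$person_id, c = ev$code,
                               m = format(as.Date(ev$date), "%Y-%m")))
  expect_equal(sum(out$n_patients), nrow(triples))
})

test_that("the generated coding era shows the placeholder-to-new-code handoff", {
  cfg <- two_subtype_config(n = 1500, seed = 33)
  tabs <- generate_population(cfg)
  out <- uptake_series(tabs$coded_events,
                       date_range = c("2020-01-01", "2022-05-31"))
  pre <- out$month < cfg$coding_switch_date
  b_pre <- sum(out$n_patients[pre & out$code == "B94.8"])
  u_pre <- sum(out$n_patients[pre & out$code == "U09.9"])
  expect_gt(b_pre, u_pre)
  post2 <- out$month >= cfg$coding_switch_date &
    out$month < cfg$coding_switch_date + 62
  b_post <- sum(out$n_patients[post2 & out$code == "B94.8"])
  u_post <- sum(out$n_patients[post2 & out$code == "U09.9"])
  expect_gt(u_post, b_post)
})
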
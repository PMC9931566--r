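test_that("invalid configurations are rejected with the offending field named", {
  expect_error(generator_config(age_group_weights = c(0.5, 0.5, 0.2, 0.1)),
               "age_group_weights")
  bad_profiles <- list(a = c(Fatigue = 1.2))
  expect_error(
    generator_config(subtype_profiles = bad_profiles,
                     subtype_mixture_by_age = matrix(1, 4, 1,
                                                     dimnames = list(NULL, "a"))),
    "subtype_profiles\\[a\\]")
  expect_error(
    generator_config(subtype_profiles = list(a = c(Fatigue = 0.5),
                                             b = c(Cough = 0.5)),
                     subtype_mixture_by_age = matrix(0.6, 4, 2)),
    "subtype_mixture_by_age")
  expect_error(generator_config(frac_inpatient_index = 1.3),
               "frac_inpatient_index")
  expect_error(generator_config(index_window_start = "2022-06-01",
                                index_window_end = "2022-01-01"),
               "index_window_start")
})

test_that("zero patients yields empty tables without error", {
  tabs <- generate_population(generator_config(n_patients = 0))
  for (nm in c("persons", "coded_events", "visits", "tests", "truth")) {
    expect_equal(nrow(tabs[[nm]]), 0)
  }
})

test_that("a forced emission probability of 1 puts the condition in every window", {
  cfg <- generator_config(
    n_patients = 200,
    subtype_profiles = list(only = c(Fatigue = 1.0)),
    subtype_mixture_by_age = matrix(1, 4, 1, dimnames = list(NULL, "only")),
    background_condition_rate = 0, seed = 3)
  tabs <- generate_population(cfg)
  fatigue <- tabs$coded_events[tabs$coded_events$code == "Fatigue", ]
  expect_setequal(unique(fatigue$person_id), tabs$persons$person_id)
})

test_that("within-subtype condition frequencies match configured emission", {
  # binomial count oracle: in-window presence per condition is Bernoulli
  # with p = emission + background; the empirical within-subtype frequency
  # must land within 3 standard errors of p
  cfg <- two_subtype_config(n = 2000, seed = 21)
  tabs <- generate_population(cfg)
  cohort <- build_cohort(tabs)
  we <- cohort$windowed
  truth <- tabs$truth
  p_expected <- 0.5 + cfg$background_condition_rate
  for (s in c("alpha", "beta")) {
    ids <- intersect(truth$person_id[truth$subtype == s],
                     included(cohort$cohort)$person_id)
    conds <- names(cfg$subtype_profiles[[s]])
    for (cond in conds[c(1, 4)]) {
      hit <- length(unique(we$person_id[we$code == cond &
                                          we$person_id %in% ids]))
      phat <- hit / length(ids)
      se <- sqrt(p_expected * (1 - p_expected) / length(ids))
      expect_lt(abs(phat - p_expected), 3 * se)
    }
  }
})

test_that("identical config and seed reproduce byte-identical tables", {
  cfg <- two_subtype_config(n = 300, seed = 9)
  t1 <- generate_population(cfg)
  t2 <- generate_population(cfg)
  expect_identical(t1, t2)
})

test_that("every patient carries exactly one latent subtype", {
  tabs <- generate_population(two_subtype_config(n = 500, seed = 2))
  expect_equal(nrow(tabs$truth), 500)
  expect_equal(anyDuplicated(tabs$truth$person_id), 0)
  expect_true(all(tabs$truth$subtype %in% c("alpha", "beta")))
})

test_that("generated age-group proportions match the configured weights", {
  cfg <- generator_config(n_patients = 10000, seed = 13)
  tabs <- generate_population(cfg)
  obs <- table(factor(tabs$truth$age_group, levels = c("<21", "21-45",
                                                       "46-65", "66+")))
  gof <- suppressWarnings(chisq.test(obs, p = cfg$age_group_weights))
  expect_gt(gof$p.value, 0.001)
})

test_that("coded events reference existing persons and dates parse", {
  tabs <- generate_population(two_subtype_config(n = 400, seed = 8))
  expect_true(all(tabs$coded_events$person_id %in% tabs$persons$person_id))
  expect_no_error(parse_dates <- as.Date(tabs$coded_events$date))
  vis_start <- as.Date(tabs$visits$start_date)
  vis_end <- as.Date(tabs$visits$end_date)
  expect_true(all(vis_end >= vis_start))
})

test_that("placeholder-era events precede the coding switch and index events follow it", {
  cfg <- two_subtype_config(n = 500, seed = 4)
  tabs <- generate_population(cfg)
  b948 <- as.Date(tabs$coded_events$date[tabs$coded_events$code == "B94.8"])
  u099 <- as.Date(tabs$coded_events$date[tabs$coded_events$code == "U09.9"])
  expect_gt(length(b948), 0)
  expect_true(all(b948 < cfg$coding_switch_date))
  expect_true(all(u099 >= cfg$coding_switch_date))
})

test_that("synthetic SDoH table honours the gradient spec", {
  # degenerate sd = 0 collapses to the mean exactly
  one <- generate_sdoh_table("10001", list(pct_poverty = c(11, 0)), seed = 1)
  expect_equal(one$pct_poverty, 11)
  # law of large numbers: 1000 ZIPs, mean within 0.5 of the target
  zips <- sprintf("%05d", 1:1000)
  tab <- generate_sdoh_table(zips, list(pct_poverty = c(11, 5)), seed = 7)
  expect_lt(abs(mean(tab$pct_poverty) - 11), 0.5)
  expect_true(all(tab$pct_poverty >= 0 & tab$pct_poverty <= 100))
  # invalid inputs
  expect_error(generate_sdoh_table(c("10001", "10001")), "duplicate")
  expect_error(generate_sdoh_table("10001", list(p = c(10, -1))), "sd")
})
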
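#' Default planted symptom-subtype emission profiles
#'
#' Five latent subtypes mirroring the condition families that cluster
#' around the long COVID index code: neurological, cardiopulmonary,
#' gastrointestinal, upper respiratory, and age-associated comorbid
#' conditions. Each subtype emits its block of conditions independently
#' with probability `emission`; conditions outside every block (e.g.
#' fever, myalgia) occur only at the background rate, giving a known
#' block structure that community detection should recover.
#'
#' @param emission within-block per-condition emission probability.
#' @return named list of named numeric vectors (condition -> probability).
#' @export
default_subtype_profiles <- function(emission = 0.5) {
  blocks <- list(
    neurological = c(
      "Fatigue", "Chronic fatigue syndrome", "Headache", "Dizziness",
      "Memory impairment", "Anxiety disorder", "Depressive disorder",
      "Insomnia"),
    cardiopulmonary = c(
      "Dyspnea", "Cough", "Chest pain", "Palpitations", "Tachycardia",
      "Hypoxemia", "Wheezing", "Asthma"),
    gastrointestinal = c(
      "Abdominal pain", "Nausea", "Vomiting", "Diarrhea",
      "Gastroesophageal reflux disease", "Constipation"),
    upper_respiratory = c(
      "Acute pharyngitis", "Acute upper respiratory infection",
      "Nasal congestion", "Sinusitis", "Anosmia", "Dysgeusia"),
    comorbid = c(
      "Essential hypertension", "Type 2 diabetes mellitus",
      "Hyperlipidemia", "Obesity", "Congestive heart failure",
      "Atrial fibrillation", "Coronary atherosclerosis",
      "Chronic obstructive pulmonary disease")
  )
  lapply(blocks, function(conds) setNames(rep(emission, length(conds)), conds))
}

#' Planted condition block labels implied by a set of subtype profiles
#'
#' Assigns each condition appearing in any profile to the subtype with its
#' maximum emission probability. This is the ground-truth partition that
#' stratified community detection is expected to recover.
#'
#' @param profiles list of named emission vectors (see
#'   [default_subtype_profiles()]).
#' @return named character vector: condition -> subtype label.
#' @export
subtype_condition_blocks <- function(profiles) {
  conds <- unique(unlist(lapply(profiles, names)))
  emis <- sapply(profiles, function(p) {
    v <- setNames(numeric(length(conds)), conds)
    v[names(p)] <- p
    v
  })
  emis <- matrix(emis, nrow = length(conds),
                 dimnames = list(conds, names(profiles)))
  keep <- apply(emis, 1, max) > 0
  out <- colnames(emis)[apply(emis[keep, , drop = FALSE], 1, which.max)]
  setNames(out, conds[keep])
}

default_age_mixtures <- function(subtypes) {
  full <- rbind(
    "<21"   = c(neurological = 0.30, cardiopulmonary = 0.15,
                gastrointestinal = 0.20, upper_respiratory = 0.30,
                comorbid = 0.05),
    "21-45" = c(neurological = 0.40, cardiopulmonary = 0.30,
                gastrointestinal = 0.15, upper_respiratory = 0.05,
                comorbid = 0.10),
    "46-65" = c(neurological = 0.30, cardiopulmonary = 0.35,
                gastrointestinal = 0.10, upper_respiratory = 0.05,
                comorbid = 0.20),
    "66+"   = c(neurological = 0.15, cardiopulmonary = 0.30,
                gastrointestinal = 0.05, upper_respiratory = 0.05,
                comorbid = 0.45)
  )
  m <- full[, subtypes, drop = FALSE]
  sweep(m, 1, rowSums(m), "/")
}

#' Synthetic-population generator configuration
#'
#' Defines the study conditions emulated by [generate_population()]:
#' age-group marginals matching the published cohort breakdown, a latent
#' per-patient symptom subtype drawn from an age-specific mixture,
#' conditionally independent condition emission within the 60-day
#' analysis window, exact-count allocation of the inpatient-index,
#' acute-hospitalization, severe, and missing-COVID-index subsets, a
#' ZIP-linked social-deprivation gradient, and a placeholder-code era
#' (B94.8) before the index code's release date.
#'
#' @param n_patients number of patients to generate.
#' @param age_group_weights probabilities over the four age bins
#'   `<21, 21-45, 46-65, 66+`; must sum to 1. Defaults are the published
#'   cohort proportions (2316, 11364, 13850, 6252 of 33782).
#' @param subtype_profiles named list of per-condition emission
#'   probability vectors, one per latent subtype.
#' @param subtype_mixture_by_age 4 x n_subtypes matrix of mixture
#'   probabilities (rows = age groups, each summing to 1).
#' @param background_condition_rate per-condition probability applied to
#'   every patient regardless of subtype.
#' @param frac_inpatient_index fraction of patients whose index date falls
#'   inside an inpatient stay (excluded downstream).
#' @param frac_hospitalized_acute fraction of the base (non-excluded)
#'   population hospitalized during the prior acute infection.
#' @param frac_severe_acute fraction of the hospitalized with a severe
#'   stay (ventilator/ECMO/vasopressors).
#' @param frac_missing_covid_index fraction of the base population with no
#'   acute COVID index date on record.
#' @param frac_deceased fraction deceased (default 0: the initial
#'   population is defined as non-deceased patients carrying the code).
#' @param frac_b948_era fraction of patients carrying a placeholder B94.8
#'   code dated before `coding_switch_date`.
#' @param coding_switch_date release date of the index code; B94.8 events
#'   are generated strictly before it, U09.9 events on/after it.
#' @param index_window_start,index_window_end closed interval from which
#'   index dates are drawn uniformly.
#' @param window_days length of the post-index analysis window used to
#'   date in-window events.
#' @param sdoh_skew strength of the ZIP sampling skew toward low-poverty
#'   areas (0 = uniform); emulates differential code uptake by area
#'   deprivation.
#' @param n_sites,n_zips numbers of synthetic sites and ZIP codes.
#' @param seed integer master seed; all tables derive named sub-streams
#'   from it, so output is byte-identical given the same config and seed.
#' @return validated config object (class `generator_config`).
#' @export
generator_config <- function(n_patients = 20000,
                             age_group_weights = c(2316, 11364, 13850, 6252) / 33782,
                             subtype_profiles = default_subtype_profiles(),
                             subtype_mixture_by_age = NULL,
                             background_condition_rate = 0.03,
                             frac_inpatient_index = 3098 / 36880,
                             frac_hospitalized_acute = 3266 / 33782,
                             frac_severe_acute = 791 / 3266,
                             frac_missing_covid_index = 12550 / 33782,
                             frac_deceased = 0,
                             frac_b948_era = 0.25,
                             coding_switch_date = as.Date("2021-10-01"),
                             index_window_start = as.Date("2021-10-01"),
                             index_window_end = as.Date("2022-05-26"),
                             window_days = 60,
                             sdoh_skew = 0,
                             n_sites = 5,
                             n_zips = 250,
                             seed = 1L) {
  if (is.null(subtype_mixture_by_age)) {
    subtype_mixture_by_age <- default_age_mixtures(names(subtype_profiles))
  }
  cfg <- list(
    n_patients = n_patients,
    age_group_weights = age_group_weights,
    subtype_profiles = subtype_profiles,
    subtype_mixture_by_age = subtype_mixture_by_age,
    background_condition_rate = background_condition_rate,
    frac_inpatient_index = frac_inpatient_index,
    frac_hospitalized_acute = frac_hospitalized_acute,
    frac_severe_acute = frac_severe_acute,
    frac_missing_covid_index = frac_missing_covid_index,
    frac_deceased = frac_deceased,
    frac_b948_era = frac_b948_era,
    coding_switch_date = as.Date(coding_switch_date),
    index_window_start = as.Date(index_window_start),
    index_window_end = as.Date(index_window_end),
    window_days = window_days,
    sdoh_skew = sdoh_skew,
    n_sites = n_sites,
    n_zips = n_zips,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid generator config: %s (%s)", field, msg), call. = FALSE)
  }
  if (length(cfg$n_patients) != 1 || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients)) {
    stop_field("n_patients", "must be a single non-negative integer")
  }
  w <- cfg$age_group_weights
  if (length(w) != 4 || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop_field("age_group_weights", "4 non-negative values summing to 1")
  }
  for (s in names(cfg$subtype_profiles)) {
    p <- cfg$subtype_profiles[[s]]
    if (any(p < 0 | p > 1)) {
      stop_field(sprintf("subtype_profiles[%s]", s),
                 "emission probabilities must lie in [0, 1]")
    }
  }
  m <- cfg$subtype_mixture_by_age
  if (!is.matrix(m) || nrow(m) != 4 || ncol(m) != length(cfg$subtype_profiles) ||
      any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
    stop_field("subtype_mixture_by_age",
               "4 rows of non-negative probabilities, each summing to 1")
  }
  for (f in c("background_condition_rate", "frac_inpatient_index",
              "frac_hospitalized_acute", "frac_severe_acute",
              "frac_missing_covid_index", "frac_deceased", "frac_b948_era",
              "sdoh_skew")) {
    v <- cfg[[f]]
    if (f != "sdoh_skew" && (v < 0 || v > 1)) stop_field(f, "must lie in [0, 1]")
  }
  if (cfg$index_window_start > cfg$index_window_end) {
    stop_field("index_window_start", "must be <= index_window_end")
  }
  invisible(cfg)
}

age_bins <- function() {
  list(labels = c("<21", "21-45", "46-65", "66+"),
       lower = c(0, 21, 46, 66), upper = c(21, 46, 66, 91))
}

#' Generate a synthetic area-level SDoH table
#'
#' One row per ZIP code with ACS-style percentage variables drawn from
#' independent normals and clipped to \[0, 100\]. Values are synthetic
#' stand-ins for survey estimates; only their distributional shape (a
#' gradient across areas) matters downstream.
#'
#' @param zips character vector of distinct ZIP codes.
#' @param gradient_spec named list of `c(mean, sd)` pairs, one per
#'   variable; see [default_sdoh_gradient()].
#' @param seed integer seed.
#' @return data.frame with column `zip` plus one numeric column per
#'   variable.
#' @export
generate_sdoh_table <- function(zips, gradient_spec = default_sdoh_gradient(),
                                seed = 1L) {
  if (length(zips) == 0) stop("zips must be non-empty", call. = FALSE)
  if (anyDuplicated(zips)) stop("duplicate ZIP codes in input", call. = FALSE)
  for (v in names(gradient_spec)) {
    g <- gradient_spec[[v]]
    if (length(g) < 2 || g[2] < 0) {
      stop(sprintf("gradient_spec[%s]: need c(mean, sd) with sd >= 0", v),
           call. = FALSE)
    }
  }
  with_substream(seed, "sdoh", {
    out <- data.frame(zip = as.character(zips), stringsAsFactors = FALSE)
    for (v in names(gradient_spec)) {
      g <- gradient_spec[[v]]
      out[[v]] <- pmin(100, pmax(0, rnorm(length(zips), g[1], g[2])))
    }
    out
  })
}

#' Default SDoH variable gradient
#'
#' Means and spreads (percent scale) for the four area-level variables
#' carried through the disparity analysis: household poverty, college
#' attainment, public health insurance, and unemployment.
#'
#' @return named list of `c(mean, sd)` pairs.
#' @export
default_sdoh_gradient <- function() {
  list(pct_poverty          = c(11, 5),
       pct_college          = c(14, 6),
       pct_public_insurance = c(18, 7),
       pct_unemployed       = c(4.4, 1.6))
}

empty_tables <- function() {
  chr <- character(0); num <- numeric(0); lgl <- logical(0)
  list(
    persons = data.frame(person_id = chr, birth_date = chr, sex = chr,
                         race = chr, ethnicity = chr, zip = chr,
                         deceased = lgl, site_id = chr,
                         hospitalized_acute = lgl, severe_acute = lgl,
                         covid_index_available = lgl,
                         stringsAsFactors = FALSE),
    coded_events = data.frame(person_id = chr, code = chr, vocabulary = chr,
                              date = chr, event_class = chr, inpatient = lgl,
                              stringsAsFactors = FALSE),
    visits = data.frame(person_id = chr, start_date = chr, end_date = chr,
                        inpatient = lgl, stringsAsFactors = FALSE),
    tests = data.frame(person_id = chr, date = chr, result = chr,
                       stringsAsFactors = FALSE),
    site_metadata = data.frame(site_id = chr, lab_coverage = num,
                               valid_end_frac = num, date_shift_days = num,
                               index_code_use = num, stringsAsFactors = FALSE),
    sdoh_by_zip = data.frame(zip = chr, stringsAsFactors = FALSE),
    truth = data.frame(person_id = chr, subtype = chr, age_group = chr,
                       stringsAsFactors = FALSE)
  )
}

#' Generate an OMOP-flavored synthetic population with planted truth
#'
#' Draws, for each patient, an age group, a latent symptom subtype from
#' the age group's mixture, an index date uniform over the configured
#' window, and conditionally independent condition events inside the
#' 0-60-day analysis window (subtype emission plus background rate).
#' Also emits prior-history condition noise, placeholder B94.8 events
#' before the coding switch date, procedure and drug events keyed to the
#' bundled fixtures, inpatient/outpatient visits, SARS-CoV-2 tests, site
#' metadata, a ZIP-keyed SDoH table, and a truth table with exactly one
#' subtype per patient. Output is byte-identical given the same config.
#'
#' @param config a [generator_config()].
#' @return named list of data.frames (class `raw_tables`): `persons`,
#'   `coded_events`, `visits`, `tests`, `site_metadata`, `sdoh_by_zip`,
#'   `truth`. All dates are ISO-8601 strings.
#' @export
generate_population <- function(config) {
  validate_generator_config(config)
  n <- config$n_patients
  if (n == 0) {
    return(structure(empty_tables(), class = "raw_tables"))
  }

  zips <- make_zips(config$n_zips)
  sdoh <- generate_sdoh_table(zips, seed = config$seed)

  bins <- age_bins()
  subtypes <- names(config$subtype_profiles)
  window_len <- as.integer(config$index_window_end - config$index_window_start)

  p <- with_substream(config$seed, "persons", {
    person_id <- sprintf("P%07d", seq_len(n))
    age_idx <- sample.int(4, n, replace = TRUE, prob = config$age_group_weights)
    subtype <- vapply(age_idx, function(a) {
      sample(subtypes, 1, prob = config$subtype_mixture_by_age[a, ])
    }, character(1))
    index_date <- config$index_window_start +
      sample.int(window_len + 1, n, replace = TRUE) - 1L
    age_years <- bins$lower[age_idx] +
      runif(n) * (bins$upper[age_idx] - bins$lower[age_idx])
    birth_date <- index_date - round(age_years * 365.25)
    sex <- sample(c("Female", "Male", "Unknown"), n, replace = TRUE,
                  prob = c(0.66, 0.335, 0.005))
    race <- sample(c("White", "Black", "Asian",
                     "American Indian or Alaska Native",
                     "Hawaiian/Pac Isldr", "Other", "Unknown"),
                   n, replace = TRUE,
                   prob = c(0.72, 0.14, 0.02, 0.008, 0.002, 0.01, 0.10))
    ethnicity <- sample(c("Hispanic/Latino", "Not Hispanic/Latino", "Unknown"),
                        n, replace = TRUE, prob = c(0.10, 0.80, 0.10))
    # ZIP sampling skewed toward low-poverty areas when sdoh_skew > 0
    pov <- sdoh$pct_poverty
    wz <- exp(-config$sdoh_skew * (pov - mean(pov)) / max(stats::sd(pov), 1e-9))
    zip <- sample(sdoh$zip, n, replace = TRUE, prob = wz / sum(wz))
    site_id <- sprintf("S%02d", sample.int(config$n_sites, n, replace = TRUE))

    deceased <- pick_exact(n, config$frac_deceased)
    inpatient_index <- pick_exact(n, config$frac_inpatient_index)
    base <- which(!deceased & !inpatient_index)  # the analyzable population
    hospitalized_acute <- rep(FALSE, n)
    hospitalized_acute[base] <- pick_exact(length(base),
                                           config$frac_hospitalized_acute)
    severe_acute <- rep(FALSE, n)
    hosp <- which(hospitalized_acute)
    severe_acute[hosp] <- pick_exact(length(hosp), config$frac_severe_acute)
    covid_missing <- rep(FALSE, n)
    covid_missing[base] <- pick_exact(length(base),
                                      config$frac_missing_covid_index)
    b948_era <- pick_exact(n, config$frac_b948_era)

    data.frame(person_id, birth_date, index_date, age_idx, subtype,
               sex, race, ethnicity, zip, site_id,
               deceased, inpatient_index, hospitalized_acute, severe_acute,
               covid_index_available = !covid_missing, b948_era,
               stringsAsFactors = FALSE)
  })

  events <- with_substream(config$seed, "events", {
    pieces <- list()
    # index code itself
    pieces$index <- data.frame(
      person_id = p$person_id, code = "U09.9", vocabulary = "ICD-10-CM",
      date = p$index_date, event_class = "condition",
      inpatient = p$inpatient_index, stringsAsFactors = FALSE)

    # in-window condition emission: subtype block + background
    conds <- unique(unlist(lapply(config$subtype_profiles, names)))
    all_conds <- unique(c(conds, condition_crosswalk()$snomed_name))
    emis <- matrix(config$background_condition_rate,
                   nrow = length(subtypes), ncol = length(all_conds),
                   dimnames = list(subtypes, all_conds))
    for (s in subtypes) {
      pr <- config$subtype_profiles[[s]]
      emis[s, names(pr)] <- pmin(1, emis[s, names(pr)] + pr)
    }
    probs <- emis[p$subtype, , drop = FALSE]
    hits <- which(matrix(runif(length(probs)), nrow(probs)) < probs,
                  arr.ind = TRUE)
    if (nrow(hits) > 0) {
      pieces$conditions <- data.frame(
        person_id = p$person_id[hits[, 1]],
        code = all_conds[hits[, 2]],
        vocabulary = "SNOMED",
        date = p$index_date[hits[, 1]] +
          sample.int(config$window_days + 1, nrow(hits), replace = TRUE) - 1L,
        event_class = "condition", inpatient = FALSE,
        stringsAsFactors = FALSE)
    }

    # sparse pre-index history (conditions are NOT excluded for prior
    # occurrence downstream; this exercises that rule)
    prior_rate <- 0.02
    ph <- which(matrix(runif(n * length(all_conds)), n) < prior_rate,
                arr.ind = TRUE)
    if (nrow(ph) > 0) {
      pieces$prior <- data.frame(
        person_id = p$person_id[ph[, 1]],
        code = all_conds[ph[, 2]],
        vocabulary = "SNOMED",
        date = p$index_date[ph[, 1]] -
          sample(30:365, nrow(ph), replace = TRUE),
        event_class = "condition", inpatient = FALSE,
        stringsAsFactors = FALSE)
    }

    # placeholder-code era before the switch date
    era_start <- as.Date("2020-04-01")
    who <- which(p$b948_era)
    if (length(who) > 0 && config$coding_switch_date > era_start) {
      span <- as.integer(config$coding_switch_date - era_start)
      pieces$b948 <- data.frame(
        person_id = p$person_id[who], code = "B94.8",
        vocabulary = "ICD-10-CM",
        date = era_start + sample.int(span, length(who), replace = TRUE) - 1L,
        event_class = "condition", inpatient = FALSE,
        stringsAsFactors = FALSE)
    }

    # procedures: category-level utilization plus encounter-only E&M codes
    pmap <- procedure_categories()
    rates <- c("radiography" = 0.12, "electrocardiography" = 0.17,
               "echocardiography" = 0.08, "pulmonary function testing" = 0.05,
               "physical therapy" = 0.06, "occupational therapy" = 0.03,
               "laboratory" = 0.25, "respiratory therapy" = 0.03,
               "cardiac monitoring" = 0.03, "sleep study" = 0.02,
               "behavioral health" = 0.05, "speech therapy" = 0.01,
               "infusion" = 0.02)
    proc_pieces <- lapply(names(rates), function(cat) {
      who <- which(runif(n) < rates[[cat]])
      if (length(who) == 0) return(NULL)
      codes <- pmap$code[pmap$category == cat]
      data.frame(
        person_id = p$person_id[who],
        code = sample(codes, length(who), replace = TRUE),
        vocabulary = "CPT4",
        date = p$index_date[who] +
          sample.int(config$window_days + 1, length(who), replace = TRUE) - 1L,
        event_class = "procedure", inpatient = FALSE,
        stringsAsFactors = FALSE)
    })
    em_who <- which(runif(n) < 0.6)
    if (length(em_who) > 0) {
      proc_pieces$em <- data.frame(
        person_id = p$person_id[em_who], code = "99213", vocabulary = "CPT4",
        date = p$index_date[em_who], event_class = "procedure",
        inpatient = FALSE, stringsAsFactors = FALSE)
    }
    pieces$procedures <- do.call(rbind, proc_pieces)

    # drugs at ingredient level; ~30% of in-window drugs also have a prior
    # record, exercising the new-medication exclusion rule
    amap <- atc_ingredients()
    dh <- which(matrix(runif(n * nrow(amap)), n) < 0.05, arr.ind = TRUE)
    if (nrow(dh) > 0) {
      drugs <- data.frame(
        person_id = p$person_id[dh[, 1]],
        code = amap$ingredient[dh[, 2]],
        vocabulary = "RxNorm",
        date = p$index_date[dh[, 1]] +
          sample.int(config$window_days + 1, nrow(dh), replace = TRUE) - 1L,
        event_class = "drug", inpatient = FALSE, stringsAsFactors = FALSE)
      prior_idx <- which(runif(nrow(dh)) < 0.3)
      if (length(prior_idx) > 0) {
        prior_drugs <- drugs[prior_idx, ]
        prior_drugs$date <- p$index_date[dh[prior_idx, 1]] -
          sample(30:180, length(prior_idx), replace = TRUE)
        drugs <- rbind(drugs, prior_drugs)
      }
      pieces$drugs <- drugs
    }

    ev <- do.call(rbind, pieces)
    rownames(ev) <- NULL
    ev
  })

  visits <- with_substream(config$seed, "visits", {
    pieces <- list()
    who <- which(p$inpatient_index)
    if (length(who) > 0) {
      pieces$inpatient_index <- data.frame(
        person_id = p$person_id[who],
        start_date = p$index_date[who] - sample(0:5, length(who), TRUE),
        end_date = p$index_date[who] + sample(0:10, length(who), TRUE),
        inpatient = TRUE, stringsAsFactors = FALSE)
    }
    hosp <- which(p$hospitalized_acute)
    if (length(hosp) > 0) {
      acute_start <- p$index_date[hosp] - sample(30:120, length(hosp), TRUE)
      pieces$acute <- data.frame(
        person_id = p$person_id[hosp],
        start_date = acute_start,
        end_date = acute_start + sample(3:14, length(hosp), TRUE),
        inpatient = TRUE, stringsAsFactors = FALSE)
    }
    pieces$outpatient <- data.frame(
      person_id = p$person_id, start_date = p$index_date,
      end_date = p$index_date, inpatient = FALSE, stringsAsFactors = FALSE)
    v <- do.call(rbind, pieces)
    rownames(v) <- NULL
    v
  })

  tests <- with_substream(config$seed, "tests", {
    who <- which(p$covid_index_available)
    if (length(who) == 0) {
      empty_tables()$tests
    } else {
      data.frame(person_id = p$person_id[who],
                 date = p$index_date[who] - sample(21:120, length(who), TRUE),
                 result = "positive", stringsAsFactors = FALSE)
    }
  })

  site_metadata <- with_substream(config$seed, "sites", {
    ids <- sprintf("S%02d", seq_len(config$n_sites))
    use <- table(factor(p$site_id, levels = ids))
    data.frame(site_id = ids,
               lab_coverage = round(runif(config$n_sites, 0.30, 0.90), 3),
               valid_end_frac = round(runif(config$n_sites, 0.80, 1.00), 3),
               date_shift_days = sample(0:30, config$n_sites, replace = TRUE),
               index_code_use = as.numeric(use),
               stringsAsFactors = FALSE)
  })

  iso <- function(d) format(d, "%Y-%m-%d")
  persons <- data.frame(
    person_id = p$person_id, birth_date = iso(p$birth_date), sex = p$sex,
    race = p$race, ethnicity = p$ethnicity, zip = p$zip,
    deceased = p$deceased, site_id = p$site_id,
    hospitalized_acute = p$hospitalized_acute, severe_acute = p$severe_acute,
    covid_index_available = p$covid_index_available, stringsAsFactors = FALSE)
  events$date <- iso(events$date)
  visits$start_date <- iso(visits$start_date)
  visits$end_date <- iso(visits$end_date)
  if (nrow(tests) > 0) tests$date <- iso(tests$date)
  truth <- data.frame(person_id = p$person_id, subtype = p$subtype,
                      age_group = age_bins()$labels[p$age_idx],
                      stringsAsFactors = FALSE)

  structure(list(persons = persons, coded_events = events, visits = visits,
                 tests = tests, site_metadata = site_metadata,
                 sdoh_by_zip = sdoh, truth = truth),
            class = "raw_tables")
}

make_zips <- function(n_zips) {
  sprintf("%05d", seq(10001L, by = 37L, length.out = n_zips))
}
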
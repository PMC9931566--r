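# Shared fixtures, all built in code at test time.

# Two triangles {a,b,c} and {d,e,f} joined by the single bridge c-d;
# 6 nodes, 7 unit edges. The triangle partition is the global modularity
# maximum with Q = 5/14.
two_triangle_graph <- function() {
  W <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  for (k in seq_len(nrow(edges))) {
    W[edges[k, 1], edges[k, 2]] <- 1
    W[edges[k, 2], edges[k, 1]] <- 1
  }
  W
}

# Two disconnected cliques of the given sizes (unit weights).
clique_pair_graph <- function(s1 = 4, s2 = 3) {
  n <- s1 + s2
  W <- matrix(0, n, n)
  W[1:s1, 1:s1] <- 1
  W[(s1 + 1):n, (s1 + 1):n] <- 1
  diag(W) <- 0
  rownames(W) <- colnames(W) <- paste0("n", seq_len(n))
  W
}

# Planted 2-block random graph: unit edges within blocks with prob p_in,
# between blocks with prob p_out. Returns the weight matrix and the true
# block labels.
planted_block_graph <- function(sizes = c(15, 15), p_in = 0.5, p_out = 0.05,
                                seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  truth <- rep(seq_along(sizes), sizes)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (truth[i] == truth[j]) p_in else p_out
      if (runif(1) < p) W[i, j] <- W[j, i] <- 1
    }
  }
  rownames(W) <- colnames(W) <- paste0("n", seq_len(n))
  list(W = W, truth = truth)
}

# Minimal hand-built event/person/visit tables for cohort-rule tests.
tiny_cohort_tables <- function() {
  persons <- data.frame(
    person_id = c("P1", "P2", "P3", "P4"),
    birth_date = c("1990-06-15", "2010-01-01", "1950-03-20", "1980-11-02"),
    sex = "Female", race = "White", ethnicity = "Not Hispanic/Latino",
    zip = "10001", deceased = c(FALSE, FALSE, FALSE, TRUE),
    site_id = "S01",
    hospitalized_acute = c(TRUE, FALSE, FALSE, FALSE),
    severe_acute = FALSE,
    covid_index_available = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  events <- data.frame(
    person_id = c("P1", "P1", "P2", "P3", "P4"),
    code = "U09.9", vocabulary = "ICD-10-CM",
    date = c("2021-11-01", "2022-01-05", "2021-09-15", "2022-01-10",
             "2021-12-01"),
    event_class = "condition", inpatient = FALSE, stringsAsFactors = FALSE)
  visits <- data.frame(
    person_id = "P3", start_date = "2022-01-05", end_date = "2022-01-15",
    inpatient = TRUE, stringsAsFactors = FALSE)
  list(persons = persons, events = events, visits = visits)
}

# Small two-subtype generator config with non-overlapping blocks, used by
# frequency-calibration and stability tests.
two_subtype_config <- function(n = 1500, seed = 11) {
  profiles <- list(
    alpha = setNames(rep(0.5, 6),
                     c("Fatigue", "Headache", "Dizziness", "Insomnia",
                       "Anxiety disorder", "Memory impairment")),
    beta = setNames(rep(0.5, 6),
                    c("Dyspnea", "Cough", "Chest pain", "Palpitations",
                      "Tachycardia", "Wheezing")))
  mix <- matrix(0.5, 4, 2, dimnames = list(NULL, names(profiles)))
  generator_config(n_patients = n, subtype_profiles = profiles,
                   subtype_mixture_by_age = mix,
                   background_condition_rate = 0.02, seed = seed)
}

# Four-subtype config whose 30 block conditions are recoverable from
# age-stratified networks (used by planted-recovery tests).
four_subtype_config <- function(n = 3000, seed = 5) {
  profiles <- default_subtype_profiles()
  profiles$upper_respiratory <- NULL   # 8 + 8 + 6 + 8 = 30 block conditions
  mix <- rbind(
    c(0.35, 0.20, 0.30, 0.15),
    c(0.40, 0.30, 0.15, 0.15),
    c(0.25, 0.35, 0.15, 0.25),
    c(0.15, 0.30, 0.15, 0.40))
  colnames(mix) <- names(profiles)
  generator_config(n_patients = n, subtype_profiles = profiles,
                   subtype_mixture_by_age = mix,
                   background_condition_rate = 0.03, seed = seed)
}

# Convenience: generator output -> included cohort + windowed events.
build_cohort <- function(tabs, rule = index_rule()) {
  idx <- derive_index(tabs$coded_events, rule)
  cohort <- apply_exclusions(tabs$persons, tabs$visits, idx)
  list(cohort = cohort,
       windowed = window_events(cohort, tabs$coded_events, rule$window_days))
}
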
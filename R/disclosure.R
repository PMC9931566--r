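#' Disclosure policy for small-cell suppression
#'
#' Counts strictly below `threshold` (but above zero) are suppressed and
#' displayed as `"<20"`-style strings; where a suppressed cell would be
#' derivable from a displayed margin, one displayed complement count is
#' shifted by a nonzero random amount of magnitude at most `shift_max`.
#'
#' @param threshold suppression threshold; a count of exactly
#'   `threshold` is displayed (the rule is strictly-less-than).
#' @param shift_max maximum absolute shift (default 5).
#' @param seed integer seed for the shift draws; reruns with the same
#'   seed reproduce the same shifts.
#' @return a `disclosure_policy` object.
#' @export
disclosure_policy <- function(threshold = 20, shift_max = 5, seed = 1L) {
  structure(list(threshold = threshold, shift_max = shift_max,
                 seed = as.integer(seed)),
            class = "disclosure_policy")
}

#' Apply suppression and complement shifting to one count group
#'
#' A "group" is one variable within one age-group column: a vector of
#' category counts whose total is displayed as the column margin. Cells
#' in `[1, threshold)` are suppressed. If any cell is suppressed and at
#' least one cell is displayed, the smallest displayed cell is shifted by
#' a draw from \{+/-1 .. +/-shift_max\}, constrained so (a) the shifted
#' display never falls below the threshold and (b) when exactly one cell
#' is suppressed, the candidate set an attacker could derive for it from
#' the displayed margin never collapses to a single value. Percentages
#' downstream use the shifted counts, as the displayed table must be
#' internally consistent.
#'
#' @param counts non-negative integer vector of category counts.
#' @param policy a [disclosure_policy()].
#' @param stream character scalar naming the RNG sub-stream for this
#'   group (so shifts are stable per table cell across reruns).
#' @return data.frame with columns `count` (true), `suppressed`,
#'   `shift` (0 where not shifted), `count_displayed` (NA where
#'   suppressed), `display` (character).
#' @export
apply_disclosure <- function(counts, policy = disclosure_policy(),
                             stream = "group") {
  th <- policy$threshold
  suppressed <- counts >= 1 & counts < th
  shift <- rep(0L, length(counts))
  displayed <- which(!suppressed)
  if (any(suppressed) && length(displayed) > 0 &&
      any(counts[displayed] > 0)) {
    vis <- displayed[counts[displayed] > 0]
    target <- vis[which.min(counts[vis])]
    cand <- setdiff(seq(-policy$shift_max, policy$shift_max), 0L)
    # keep the shifted display out of the suppressed range
    cand <- cand[counts[target] + cand >= th]
    if (sum(suppressed) == 1) {
      # drop shifts that would let the derived candidate set collapse to
      # one value (suppressed cell 1 with s = +max, or th-1 with s = -max)
      v <- counts[suppressed]
      if (v == 1) cand <- setdiff(cand, policy$shift_max)
      if (v == th - 1) cand <- setdiff(cand, -policy$shift_max)
    }
    if (length(cand) > 0) {
      shift[target] <- with_substream(policy$seed, stream,
                                      cand[sample.int(length(cand), 1)])
    }
  }
  count_displayed <- ifelse(suppressed, NA_integer_,
                            as.integer(counts + shift))
  display <- ifelse(suppressed, sprintf("<%d", th),
                    as.character(count_displayed))
  data.frame(count = counts, suppressed = suppressed, shift = shift,
             count_displayed = count_displayed, display = display,
             stringsAsFactors = FALSE)
}

#' Suppression-safe demographic table
#'
#' Stratified counts of person-level demographics (sex, race, ethnicity)
#' and area-level SDoH categories by age group, with small-cell
#' suppression and bounded complement shifts applied independently within
#' each variable x age-group column (see [apply_disclosure()]).
#' Percentages are computed from the shifted counts against the stratum
#' size.
#'
#' @param cohort output of [apply_exclusions()] (included rows are used).
#' @param persons persons table with `sex`, `race`, `ethnicity`, `zip`.
#' @param sdoh_categorizations named list of [categorize_sdoh()] results
#'   (may be empty).
#' @param policy a [disclosure_policy()].
#' @return a `disclosure_table`: data.frame with columns `variable`,
#'   `category`, `age_group`, `count`, `suppressed`, `shift`,
#'   `count_displayed`, `display`, `percent`, plus attribute `stratum_n`
#'   (named vector of age-group sizes).
#' @export
demographic_table <- function(cohort, persons,
                              sdoh_categorizations = list(),
                              policy = disclosure_policy()) {
  inc <- included(cohort)
  per <- persons[match(inc$person_id, persons$person_id), , drop = FALSE]
  groups <- age_bins()$labels
  stratum_n <- setNames(vapply(groups, function(g) sum(inc$age_group == g),
                               numeric(1)), groups)

  vars <- list(sex = per$sex, race = per$race, ethnicity = per$ethnicity)
  for (v in names(sdoh_categorizations)) {
    vars[[v]] <- lookup_sdoh(sdoh_categorizations[[v]], per$zip)
  }

  out <- list()
  for (v in names(vars)) {
    cats <- sort(unique(vars[[v]]))
    for (g in groups) {
      counts <- vapply(cats, function(cat) {
        sum(vars[[v]] == cat & inc$age_group == g)
      }, numeric(1))
      disc <- apply_disclosure(counts, policy,
                               stream = sprintf("demo/%s/%s", v, g))
      disc <- cbind(data.frame(variable = v, category = cats, age_group = g,
                               stringsAsFactors = FALSE), disc)
      disc$percent <- pct(disc$count_displayed, stratum_n[[g]])
      out[[length(out) + 1]] <- disc
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "stratum_n") <- stratum_n
  class(res) <- c("disclosure_table", "data.frame")
  res
}
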
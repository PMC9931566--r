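#!/usr/bin/env Rscript
# Stage 2: build the index-code cohort.
#
# Applies the site data-quality gates, derives each person's index date
# (earliest qualifying code inside the Oct 2021 - May 2022 release
# window), excludes deceased and inpatient-index patients, restricts
# events to the 0-60-day analysis window, and writes the cohort, the
# windowed events, and the attrition/headline summary.

library(lcnet)

tabs <- read_tables("results/raw")
rule <- index_rule()

eligible <- filter_sites(tabs$site_metadata)
cat(sprintf("sites passing quality gates: %d of %d\n",
            length(eligible), nrow(tabs$site_metadata)))

idx <- derive_index(tabs$coded_events, rule)
keep <- tabs$persons$person_id[tabs$persons$site_id %in% eligible]
idx <- idx[idx$person_id %in% keep, , drop = FALSE]

cohort <- apply_exclusions(tabs$persons, tabs$visits, idx)
windowed <- window_events(cohort, tabs$coded_events, rule$window_days)
s <- summarize_cohort(cohort)
print(s)

dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)
write.csv(as.data.frame(cohort), "results/cohort/cohort.csv",
          row.names = FALSE)
write.csv(windowed, "results/cohort/windowed_events.csv", row.names = FALSE)
write.csv(data.frame(key = names(unclass(s)),
                     value = unlist(unclass(s), use.names = FALSE)),
          "results/cohort/summary.csv", row.names = FALSE)
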
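#!/usr/bin/env Rscript
# Stage 5: procedures, new medications, and code-uptake series.
#
# Categorizes informative in-window procedures into high-level classes
# with the figure-style suppression rule (<20 patients or <1.0% of the
# stratum), rolls newly started medications up to ATC level 3, and
# tabulates the monthly handoff from the placeholder code (B94.8) to the
# index code (U09.9).

library(lcnet)

tabs <- read_tables("results/raw")
cohort <- read.csv("results/cohort/cohort.csv",
                   colClasses = c(person_id = "character"))
cohort$index_date <- as.Date(cohort$index_date)
windowed <- read.csv("results/cohort/windowed_events.csv",
                     colClasses = c(person_id = "character"))

dir.create("results/summaries", showWarnings = FALSE, recursive = TRUE)

procs <- filter_informative_procedures(windowed)
cat(sprintf("encounter-only procedure records removed: %d\n",
            sum(windowed$event_class == "procedure") -
              sum(procs$event_class == "procedure")))
proc_tab <- categorize_procedures(procs, cohort)
write.csv(proc_tab, "results/summaries/procedures.csv", row.names = FALSE)
shown <- proc_tab[!proc_tab$suppressed, ]
cat(sprintf("procedure categories shown: %d of %d (suppression: <20 or <1.0%%)\n",
            nrow(shown), nrow(proc_tab)))
print(head(shown[order(-shown$n_patients),
                 c("category", "age_group", "n_patients", "percent")], 8),
      row.names = FALSE)

idx <- included(cohort)[, c("person_id", "index_date")]
new_rx <- new_medications(tabs$coded_events, idx)
atc <- atc_rollup(new_rx, cohort)
write.csv(atc, "results/summaries/atc_classes.csv", row.names = FALSE)
cat(sprintf("newly started medications: %d events across %d ATC level-3 classes\n",
            nrow(new_rx), length(unique(atc$atc3))))

uptake <- uptake_series(tabs$coded_events)
write.csv(uptake, "results/summaries/uptake.csv", row.names = FALSE)
switch_month <- as.Date("2021-10-01")
pre <- subset(uptake, month < switch_month)
post <- subset(uptake, month >= switch_month)
cat(sprintf("placeholder B94.8 patients before release: %d; U09.9 before: %d\n",
            sum(pre$n_patients[pre$code == "B94.8"]),
            sum(pre$n_patients[pre$code == "U09.9"])))
cat(sprintf("after release: B94.8 %d, U09.9 %d (the new code supplants the placeholder)\n",
            sum(post$n_patients[post$code == "B94.8"]),
            sum(post$n_patients[post$code == "U09.9"])))
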
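#!/usr/bin/env Rscript
# Stage 1: simulate the study populations.
#
# Two OMOP-flavored synthetic populations are generated with known ground
# truth: (1) the index-code cohort, whose ZIP sampling is skewed toward
# low-deprivation areas (emulating differential uptake of a new diagnosis
# code), and (2) an unskewed comparator population standing in for all
# SARS-CoV-2-positive patients at the same sites. Tables are written as
# delimited text under results/raw/ and results/raw_comparator/.

library(lcnet)

cfg <- generator_config(n_patients = 20000, sdoh_skew = 0.6, seed = 20211001)
cfg_cmp <- generator_config(n_patients = 30000, sdoh_skew = 0,
                            frac_inpatient_index = 0, seed = 20211001)

tabs <- generate_population(cfg)
cmp <- generate_population(cfg_cmp)

write_tables(tabs, "results/raw", seed = cfg$seed)
write_tables(cmp, "results/raw_comparator", seed = cfg_cmp$seed)

cat(sprintf("index-code population: %d persons, %d coded events, %d visits\n",
            nrow(tabs$persons), nrow(tabs$coded_events), nrow(tabs$visits)))
cat(sprintf("comparator population: %d persons\n", nrow(cmp$persons)))
cat(sprintf("subtype mix: %s\n",
            paste(sprintf("%s=%d", names(table(tabs$truth$subtype)),
                          table(tabs$truth$subtype)), collapse = ", ")))
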
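#!/usr/bin/env Rscript
# Step 2 — score the cohort.
#
# Reads the blinded cohort, derives each subject's baseline body mass (mean
# of the three euhydrated first-morning masses), scores every visit with the
# WUT Venn diagram (body-mass loss > 1%, urine colour >= 5, thirst >= 5),
# and makes the binary reference calls (USG >= 1.020, urine osmolality
# > 700 mOsm/kg, plasma osmolality > 290 mOsm/kg).

suppressPackageStartupMessages(library(wutdiag))

visits <- read_visits("results/cohort.csv")
baselines <- compute_baseline_bm(visits)
wut <- score_wut(visits, baselines)
ref <- classify_reference(visits)

readr::write_csv(baselines, "results/baselines.csv")
readr::write_csv(wut, "results/wut.csv")
readr::write_csv(ref, "results/reference_calls.csv", na = "")

message(sprintf("scored %d visits against %d subject baselines",
                nrow(wut), nrow(baselines)))
message("WUT category counts (timepoint x condition):")
print(as.data.frame(wut_category_table(wut)))
message(sprintf("reference calls: %d (of which %d missing plasma)",
                nrow(ref), sum(is.na(ref$dehydrated))))
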
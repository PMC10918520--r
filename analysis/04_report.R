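#!/usr/bin/env Rscript
# Step 4 — render the summary report.
#
# Assembles the WUT category counts and the per-stratum accuracy metrics
# into the deterministic plain-text report, with '*' marking values passing
# the practical-significance rule (>= cut-off determination value and
# > 0.800).

suppressPackageStartupMessages(library(wutdiag))

wut <- readr::read_csv("results/wut.csv", show_col_types = FALSE)
metrics <- readr::read_csv("results/metrics.csv", na = "",
                           show_col_types = FALSE)

lines <- render_report(metrics, wut_category_table(wut),
                       meta = c(source = "results/cohort.csv"))
write_report(lines, "results/report.txt")

message(sprintf("wrote results/report.txt (%d lines); head:", length(lines)))
cat(utils::head(lines, 20), sep = "\n")
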
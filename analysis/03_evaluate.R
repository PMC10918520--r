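#!/usr/bin/env Rscript
# Step 3 — diagnostic accuracy of the WUT thresholds.
#
# Cross-tabulates the thresholded WUT score (>= 1, 2, 3 markers) against
# each reference standard within every stratum (morning/afternoon x EUH/FL,
# plus pooled), computes sensitivity, specificity, PPV, NPV and the Youden
# cut-off determination value, and exports the ROC operating points.

suppressPackageStartupMessages(library(wutdiag))

wut <- readr::read_csv("results/wut.csv", show_col_types = FALSE)
ref <- readr::read_csv("results/reference_calls.csv", na = "",
                       show_col_types = FALSE)

metrics <- evaluate_accuracy(wut, ref, criterion = "youden")
readr::write_csv(metrics, "results/metrics.csv", na = "")

roc <- dplyr::bind_rows(lapply(c("USG", "UOSM", "POSM"), function(mk) {
  dplyr::bind_rows(lapply(c("morning", "afternoon", "both"), function(tp) {
    roc_points(wut, ref, mk, timepoint = tp)
  }))
}))
readr::write_csv(roc, "results/roc_points.csv", na = "")

pooled <- dplyr::filter(metrics, timepoint == "both", condition == "both")
message("pooled operating points (both timepoints, both conditions):")
print(as.data.frame(pooled[, c("marker", "k", "TP", "FP", "FN", "TN",
                               "sensitivity", "specificity", "ppv", "npv",
                               "cutoff_value", "cutoff_k")]), digits = 3)
message(sprintf(
  "high specificity at WUT>=2 and WUT>=3 for all markers: %s",
  all(pooled$specificity[pooled$k >= 2] > 0.8)
))
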
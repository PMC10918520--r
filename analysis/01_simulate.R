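#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates the synthetic hydration cohort with the emulated design: 24
# participants (12 M / 12 F), free-living then euhydrated conditions, 3
# consecutive days, morning and afternoon spot samples (288 visits), then
# removes 17 plasma osmolality values in the 6/4/4/3 stratified pattern.
# Writes a blinded cohort (no latent truth) for scoring plus a truth-bearing
# copy for the generator-validation step.

suppressPackageStartupMessages(library(wutdiag))

seed <- 20240414 %% 1000003  # fixed study seed
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(rng_seed = seed)
visits <- inject_missingness(simulate_cohort(cfg), cfg)

write_visits(visits, "results/cohort.csv")                    # blinded
write_visits(visits, "results/cohort_truth.csv", with_truth = TRUE)

message(sprintf("simulated %d visits (%d subjects); seed %d", nrow(visits),
                length(unique(visits$subject_id)), seed))
message(sprintf("urine-analysable records: %d; plasma-analysable: %d",
                sum(!is.na(visits$usg)), sum(!is.na(visits$p_osm))))
message(sprintf("euhydration screen holds: all EUH usg < 1.020 is %s",
                all(visits$usg[visits$condition == "EUH"] < 1.020)))
message(sprintf("latent dehydration prevalence: %.1f%% (FL) / %.1f%% (EUH)",
                100 * mean(visits$latent_dehydrated[visits$condition == "FL"]),
                100 * mean(visits$latent_dehydrated[visits$condition == "EUH"])))
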
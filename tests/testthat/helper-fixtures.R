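# Shared fixtures and independent brute-force oracles.
# The oracles deliberately avoid package internals: plain loops and paste()
# keys, so agreement with the package is a real cross-check.

small_cohort <- function(seed = 1, ...) {
  cfg <- sim_config(rng_seed = seed, ...)
  visits <- inject_missingness(simulate_cohort(cfg), cfg)
  list(cfg = cfg, visits = visits)
}

visit_key_str <- function(df) {
  paste(df$subject_id, df$condition, df$day, df$timepoint, sep = "|")
}

# Brute-force 2x2 counts and metrics from raw per-visit rows.
oracle_accuracy <- function(wut_results, reference_calls, marker, k,
                            timepoint = "both", condition = "both") {
  calls <- reference_calls[reference_calls$marker == marker, ]
  ref <- setNames(calls$dehydrated, visit_key_str(calls))
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(wut_results))) {
    if (timepoint != "both" && wut_results$timepoint[i] != timepoint) next
    if (condition != "both" && wut_results$condition[i] != condition) next
    d <- ref[[visit_key_str(wut_results[i, ])]]
    if (is.na(d)) next
    pos <- wut_results$wut_count[i] >= k
    if (pos && d) tp <- tp + 1L
    else if (pos && !d) fp <- fp + 1L
    else if (!pos && d) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(
    TP = tp, FP = fp, FN = fn, TN = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

# Random scored fixture built directly (no generator): n visits with random
# WUT counts and random reference calls for all three markers.
random_scored_fixture <- function(n = 40) {
  key <- tibble::tibble(
    subject_id = sprintf("S%02d", sample(1:12, n, replace = TRUE)),
    condition = sample(c("FL", "EUH"), n, replace = TRUE),
    day = sample(1:6, n, replace = TRUE),
    timepoint = sample(c("morning", "afternoon"), n, replace = TRUE)
  )
  key <- key[!duplicated(key), ]
  n <- nrow(key)
  wut <- dplyr::bind_cols(key, tibble::tibble(wut_count = sample(0:3, n, TRUE)))
  ref <- dplyr::bind_rows(lapply(c("USG", "UOSM", "POSM"), function(mk) {
    dplyr::bind_cols(key, tibble::tibble(
      marker = mk,
      dehydrated = sample(c(TRUE, FALSE, NA), n, TRUE, prob = c(.4, .5, .1))
    ))
  }))
  list(wut = wut, ref = ref)
}
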
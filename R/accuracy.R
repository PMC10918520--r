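#' 2x2 contingency table for one marker, WUT threshold and stratum
#'
#' Cross-tabulates the thresholded WUT call (test-positive when
#' `wut_count >= k`) against one reference standard (positive =
#' reference-dehydrated) within a stratum. Visits whose reference call is
#' missing are excluded from that marker's table only (listwise per
#' marker), so urinary tables keep full design totals while plasma tables
#' shrink by the missing samples.
#'
#' @param wut_results scored visits from [score_wut()].
#' @param reference_calls long calls from [classify_reference()].
#' @param marker one of `"USG"`, `"UOSM"`, `"POSM"`.
#' @param k WUT threshold, 1, 2 or 3.
#' @param timepoint,condition stratum selectors (`"both"` pools).
#' @return one-row tibble: `marker`, `k`, `timepoint`, `condition`, `TP`,
#'   `FP`, `FN`, `TN`, `n_scorable`. An empty stratum yields a table of
#'   zeros with a warning.
#' @export
build_contingency <- function(wut_results, reference_calls, marker, k,
                              timepoint = "both", condition = "both") {
  if (!(marker %in% REF_MARKERS))
    abort(sprintf("unknown reference marker: %s", marker),
          class = "wutdiag_input_error")
  if (length(k) != 1 || is.na(k) || !(k %in% 1:3))
    abort("`k` must be 1, 2 or 3", class = "wutdiag_input_error")

  calls <- reference_calls[reference_calls$marker == marker, , drop = FALSE]
  joined <- inner_join(
    wut_results[, c(VISIT_KEY, "wut_count")],
    calls[, c(VISIT_KEY, "dehydrated")],
    by = VISIT_KEY
  )
  joined <- filter_stratum(joined, timepoint, condition)
  joined <- joined[!is.na(joined$dehydrated), , drop = FALSE]
  if (nrow(joined) == 0)
    warn(sprintf("empty stratum (timepoint=%s, condition=%s) for %s: table of zeros",
                 timepoint, condition, marker))

  test_pos <- joined$wut_count >= k
  tibble(
    marker = marker, k = as.integer(k),
    timepoint = timepoint, condition = condition,
    TP = sum(test_pos & joined$dehydrated),
    FP = sum(test_pos & !joined$dehydrated),
    FN = sum(!test_pos & joined$dehydrated),
    TN = sum(!test_pos & !joined$dehydrated),
    n_scorable = nrow(joined)
  )
}

safe_ratio <- function(num, den, reason) {
  if (den == 0) list(value = NA_real_, reason = reason)
  else list(value = num / den, reason = NA_character_)
}

#' Accuracy metrics from a 2x2 table
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)`, and Youden's
#' J (`sensitivity + specificity - 1`). A zero denominator yields `NA` with
#' an explicit reason in the matching `*_reason` column — never a silent 0
#' or NaN. The returned tibble carries an `interpretation` attribute
#' recording the reading used throughout: high sensitivity means the WUT
#' diagram accurately determines euhydration (a negative call rules
#' dehydration out), high specificity that it accurately determines
#' dehydration (a positive call rules it in).
#'
#' @param table one-row contingency tibble from [build_contingency()] (or
#'   any list with `TP`, `FP`, `FN`, `TN`).
#' @return one-row tibble with the table's identifying columns (if
#'   present), the four counts, the five metrics and four `*_reason`
#'   columns.
#' @examples
#' compute_metrics(tibble::tibble(TP = 9, FP = 1, FN = 2, TN = 8))
#' @export
compute_metrics <- function(table) {
  counts <- c(TP = table$TP, FP = table$FP, FN = table$FN, TN = table$TN)
  if (any(is.na(counts)) || any(counts < 0))
    abort("contingency counts must be non-negative", class = "wutdiag_input_error")

  sens_r <- safe_ratio(counts["TP"], counts["TP"] + counts["FN"],
                       "no reference-positive visits")
  spec_r <- safe_ratio(counts["TN"], counts["TN"] + counts["FP"],
                       "no reference-negative visits")
  ppv_r <- safe_ratio(counts["TP"], counts["TP"] + counts["FP"],
                      "no test-positive visits")
  npv_r <- safe_ratio(counts["TN"], counts["TN"] + counts["FN"],
                      "no test-negative visits")

  id_cols <- intersect(c("marker", "k", "timepoint", "condition"), names(table))
  out <- dplyr::bind_cols(
    if (length(id_cols)) as_tibble(table)[, id_cols] else tibble(.rows = 1),
    tibble(
      TP = unname(counts["TP"]), FP = unname(counts["FP"]),
      FN = unname(counts["FN"]), TN = unname(counts["TN"]),
      sensitivity = unname(sens_r$value), specificity = unname(spec_r$value),
      ppv = unname(ppv_r$value), npv = unname(npv_r$value),
      youden_j = unname(sens_r$value + spec_r$value - 1),
      sensitivity_reason = sens_r$reason, specificity_reason = spec_r$reason,
      ppv_reason = ppv_r$reason, npv_reason = npv_r$reason
    )
  )
  attr(out, "interpretation") <- paste(
    "high sensitivity: WUT accurately determines euhydration (negative call",
    "rules dehydration out); high specificity: WUT accurately determines",
    "dehydration (positive call rules it in)"
  )
  out
}

#' ROC operating points for the WUT thresholds
#'
#' The thresholded WUT score admits exactly three operating points, one per
#' threshold `k` in 1..3 (test-positive when `wut_count >= k`). Returns the
#' three points in ROC coordinates (1 - specificity, sensitivity), ordered
#' from the most specific (k = 3) to the most sensitive (k = 1), framed by
#' the trivial anchors (0, 0) ("never positive") and (1, 1) ("always
#' positive"). A stratum lacking reference-positive or reference-negative
#' visits yields `NA` coordinates with a reason instead of a guess.
#'
#' @inheritParams build_contingency
#' @return tibble: `marker`, `timepoint`, `condition`, `point`
#'   (`"anchor_00"`, `"WUT3"`, `"WUT2"`, `"WUT1"`, `"anchor_11"`), `k`
#'   (`NA` for anchors), `fpr`, `tpr`, `reason`.
#' @export
roc_points <- function(wut_results, reference_calls, marker,
                       timepoint = "both", condition = "both") {
  pts <- lapply(3:1, function(k) {
    m <- compute_metrics(build_contingency(wut_results, reference_calls,
                                           marker, k, timepoint, condition))
    reason <- paste(stats::na.omit(c(m$sensitivity_reason, m$specificity_reason)),
                    collapse = "; ")
    tibble(
      marker = marker, timepoint = timepoint, condition = condition,
      point = paste0("WUT", k), k = as.integer(k),
      fpr = 1 - m$specificity, tpr = m$sensitivity,
      reason = if (nzchar(reason)) reason else NA_character_
    )
  })
  anchor <- function(name, x, y) tibble(
    marker = marker, timepoint = timepoint, condition = condition,
    point = name, k = NA_integer_, fpr = x, tpr = y, reason = NA_character_
  )
  bind_rows(c(list(anchor("anchor_00", 0, 0)), pts, list(anchor("anchor_11", 1, 1))))
}

#' Cut-off determination value over the WUT operating points
#'
#' Summarises the three WUT operating points into a single cut-off
#' determination value computed from the sensitivity and specificity
#' values: either Youden's J (`sensitivity + specificity - 1`, maximised
#' over k) or the Euclidean distance to the perfect corner (0, 1)
#' (minimised over k). Ties break toward the larger k, i.e. the more
#' specific call. The criterion used is always echoed in the result.
#'
#' @param points output of [roc_points()] (anchors are ignored).
#' @param criterion `"youden"` (default) or `"closest_to_01"`.
#' @return list: `value` (the criterion statistic at the selected point),
#'   `k` (selected threshold), `criterion`, and `reason` (`NA` unless every
#'   operating point is undefined).
#' @examples
#' pts <- tibble::tibble(point = c("WUT1", "WUT2", "WUT3"), k = 1:3,
#'                       fpr = c(0.5, 0.1, 0), tpr = c(0.9, 0.8, 0.4))
#' cutoff_value(pts)                      # J = 0.7 at k = 2
#' cutoff_value(pts, "closest_to_01")
#' @export
cutoff_value <- function(points, criterion = c("youden", "closest_to_01")) {
  criterion <- match.arg(criterion)
  op <- points[!is.na(points$k), , drop = FALSE]
  ok <- !is.na(op$tpr) & !is.na(op$fpr)
  if (!any(ok)) {
    return(list(value = NA_real_, k = NA_integer_, criterion = criterion,
                reason = "all operating points undefined"))
  }
  op <- op[ok, , drop = FALSE]
  # ties (to within floating-point noise) break toward the larger k
  if (criterion == "youden") {
    stat <- op$tpr - op$fpr          # sens + spec - 1
    tied <- which(stat >= max(stat) - 1e-9)
  } else {
    stat <- sqrt(op$fpr^2 + (1 - op$tpr)^2)
    tied <- which(stat <= min(stat) + 1e-9)
  }
  best <- tied[which.max(op$k[tied])]
  list(value = stat[best], k = op$k[best], criterion = criterion,
       reason = NA_character_)
}

default_strata <- function() {
  tidyr::expand_grid(
    timepoint = c("morning", "afternoon", "both"),
    condition = c("EUH", "FL", "both")
  )
}

#' Full diagnostic-accuracy evaluation
#'
#' Runs [build_contingency()], [compute_metrics()] and [cutoff_value()] for
#' every combination of reference marker, WUT threshold k and stratum, and
#' applies the practical-significance flag: a sensitivity (or specificity)
#' is flagged when it reaches the stratum's cut-off determination value and
#' exceeds the flag threshold (0.800 by default). The cut-off comparison is
#' inclusive so that a perfect classifier, whose Youden J equals its
#' sensitivity and specificity, is flagged.
#'
#' @inheritParams build_contingency
#' @param markers reference markers to evaluate.
#' @param ks WUT thresholds to evaluate (subset of 1:3; the cut-off search
#'   always uses all three operating points).
#' @param strata data frame with `timepoint` and `condition` columns; the
#'   default crosses morning/afternoon/both with EUH/FL/both.
#' @param criterion cut-off criterion, see [cutoff_value()].
#' @param flag_threshold practical-significance level (default 0.800).
#' @return tibble, one row per marker x k x stratum, with counts, metrics,
#'   reasons, `cutoff_value`, `cutoff_k`, `criterion`, `flag_sensitivity`
#'   and `flag_specificity`.
#' @examples
#' cfg <- sim_config(rng_seed = 1)
#' visits <- inject_missingness(simulate_cohort(cfg), cfg)
#' metrics <- evaluate_accuracy(score_wut(visits), classify_reference(visits))
#' dplyr::filter(metrics, timepoint == "both", condition == "both")
#' @export
evaluate_accuracy <- function(wut_results, reference_calls,
                              markers = REF_MARKERS, ks = 1:3,
                              strata = default_strata(),
                              criterion = c("youden", "closest_to_01"),
                              flag_threshold = 0.800) {
  criterion <- match.arg(criterion)
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    tp <- strata$timepoint[i]
    cond <- strata$condition[i]
    for (marker in markers) {
      pts <- roc_points(wut_results, reference_calls, marker, tp, cond)
      cut <- cutoff_value(pts, criterion)
      for (k in ks) {
        m <- compute_metrics(build_contingency(wut_results, reference_calls,
                                               marker, k, tp, cond))
        m$cutoff_value <- cut$value
        m$cutoff_k <- cut$k
        m$criterion <- criterion
        m$flag_sensitivity <- !is.na(m$sensitivity) & !is.na(cut$value) &
          m$sensitivity >= cut$value & m$sensitivity > flag_threshold
        m$flag_specificity <- !is.na(m$specificity) & !is.na(cut$value) &
          m$specificity >= cut$value & m$specificity > flag_threshold
        rows[[length(rows) + 1L]] <- m
      }
    }
  }
  bind_rows(rows)
}
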
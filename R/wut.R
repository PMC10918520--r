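#' WUT dehydration thresholds
#'
#' The designated dehydration criteria for the three WUT markers: body-mass
#' loss strictly greater than 1 percent of baseline, urine colour of 5 or
#' darker on the eight-point chart, and thirst of 5 or higher on the 1-9
#' Likert scale. Note the asymmetry in comparators: the body-mass criterion
#' is strict (`>`), the colour and thirst criteria are inclusive (`>=`).
#'
#' @param bml_loss_pct percent body-mass loss threshold (met when strictly
#'   exceeded). Default 1.
#' @param u_col urine colour threshold (met at or above). Default 5.
#' @param thirst thirst threshold (met at or above). Default 5.
#' @return a `wut_thresholds` list.
#' @export
wut_thresholds <- function(bml_loss_pct = 1.0, u_col = 5L, thirst = 5L) {
  if (!is.finite(bml_loss_pct))
    abort("invalid threshold `bml_loss_pct`: must be finite")
  if (!is.finite(u_col) || u_col < 1 || u_col > 8)
    abort("invalid threshold `u_col`: must lie on the 1-8 colour chart")
  if (!is.finite(thirst) || thirst < 1 || thirst > 9)
    abort("invalid threshold `thirst`: must lie on the 1-9 scale")
  structure(list(bml_loss_pct = bml_loss_pct, u_col = u_col, thirst = thirst),
            class = "wut_thresholds")
}

#' Per-subject baseline body mass
#'
#' The reference mass for each subject is the arithmetic mean of their
#' euhydrated-condition first-morning body masses (three in the full
#' design). Subjects with fewer than three such visits keep the mean of the
#' available ones and are flagged, so externally supplied or truncated
#' datasets remain scorable; subjects with none raise an error.
#'
#' @param records visit table with `subject_id`, `condition`, `timepoint`
#'   and `body_mass_kg` columns.
#' @param subject_id optional subject(s) to restrict to; default all.
#' @return tibble: `subject_id`, `baseline_bm_kg`, `n_baseline_visits`,
#'   `baseline_flag` (`TRUE` when fewer than 3 euhydrated morning visits
#'   contributed).
#' @examples
#' visits <- simulate_cohort(sim_config(rng_seed = 1))
#' compute_baseline_bm(visits)
#' @export
compute_baseline_bm <- function(records, subject_id = NULL) {
  subjects <- if (is.null(subject_id)) unique(records$subject_id) else subject_id
  euh_am <- records[records$condition == "EUH" &
                      records$timepoint == "morning" &
                      records$subject_id %in% subjects, , drop = FALSE]
  missing_subj <- setdiff(subjects, euh_am$subject_id)
  if (length(missing_subj) > 0) {
    abort(sprintf(
      "no euhydrated morning visits to form a baseline for subject(s): %s",
      paste(missing_subj, collapse = ", ")
    ), class = "wutdiag_baseline_error")
  }
  if (anyNA(euh_am$body_mass_kg))
    abort("baseline body masses contain missing values",
          class = "wutdiag_baseline_error")
  out <- euh_am %>%
    group_by(.data$subject_id) %>%
    summarise(
      baseline_bm_kg = mean(.data$body_mass_kg),
      n_baseline_visits = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(baseline_flag = .data$n_baseline_visits < 3L)
  if (any(out$baseline_flag)) {
    warn(sprintf(
      "baseline from fewer than 3 euhydrated morning visits for: %s",
      paste(out$subject_id[out$baseline_flag], collapse = ", ")
    ))
  }
  out[match(subjects, out$subject_id), ]
}

#' Percent body-mass loss relative to baseline
#'
#' Loss-oriented percentage: `(baseline - mass) / baseline * 100`, so a mass
#' LOSS is positive and directly comparable with the "loss > 1 percent"
#' criterion. (Computed as change relative to baseline, this quantity would
#' carry the opposite sign; the loss-positive orientation is the one under
#' which the dehydration criterion is coherent, and is used throughout.)
#'
#' @param body_mass_kg measured mass(es), kg.
#' @param baseline_bm_kg baseline mass(es), kg (recycled).
#' @return numeric percent loss (negative when mass was gained).
#' @examples
#' compute_bml(79.2, 80)   #  1.0 : one percent lost
#' compute_bml(70, 68.8)   # -1.74: mass gained
#' @export
compute_bml <- function(body_mass_kg, baseline_bm_kg) {
  if (any(!is.na(body_mass_kg) & body_mass_kg <= 0) ||
      any(!is.na(baseline_bm_kg) & baseline_bm_kg <= 0))
    abort("body masses must be positive", class = "wutdiag_input_error")
  (baseline_bm_kg - body_mass_kg) / baseline_bm_kg * 100
}

wut_labels <- c("WUT0", "WUT1", "WUT2", "WUT3")
wut_interpretations <- c(
  WUT0 = "no dehydration markers met",
  WUT1 = "one dehydration marker met",
  WUT2 = "likely dehydrated",
  WUT3 = "very likely dehydrated"
)

#' Score visits with the WUT Venn diagram
#'
#' For every visit, tests the three WUT criteria — body-mass loss > 1
#' percent of the subject's baseline (strict), urine colour >= 5, thirst
#' >= 5 — and counts how many are met (0-3). Two markers met is read as
#' "likely dehydrated", three as "very likely dehydrated". WUT inputs are
#' never imputed: a missing body mass, urine colour or thirst raises an
#' error.
#'
#' @param records visit table (`subject_id`, `condition`, `day`,
#'   `timepoint`, `body_mass_kg`, `u_col`, `thirst`).
#' @param baselines per-subject baselines from [compute_baseline_bm()];
#'   computed from `records` when `NULL`.
#' @param thresholds a [wut_thresholds()].
#' @return tibble with the visit key columns plus `bml_loss_pct`, `w_met`,
#'   `u_met`, `t_met`, `wut_count`, `label` and `interpretation`.
#' @examples
#' visits <- simulate_cohort(sim_config(rng_seed = 1))
#' wut <- score_wut(visits)
#' table(wut$label)
#' @export
score_wut <- function(records, baselines = NULL, thresholds = wut_thresholds()) {
  stopifnot(inherits(thresholds, "wut_thresholds"))
  if (is.null(baselines)) baselines <- compute_baseline_bm(records)
  need <- c(VISIT_KEY, "body_mass_kg", "u_col", "thirst")
  miss_col <- setdiff(need, names(records))
  if (length(miss_col))
    abort(paste("records lack column(s):", paste(miss_col, collapse = ", ")),
          class = "wutdiag_input_error")
  for (col in c("body_mass_kg", "u_col", "thirst")) {
    if (anyNA(records[[col]])) {
      abort(sprintf(
        "missing `%s` at row(s) %s: WUT inputs are never imputed",
        col, paste(utils::head(which(is.na(records[[col]])), 5), collapse = ", ")
      ), class = "wutdiag_input_error")
    }
  }
  scored <- records %>%
    left_join(baselines[, c("subject_id", "baseline_bm_kg")], by = "subject_id")
  if (anyNA(scored$baseline_bm_kg)) {
    abort(sprintf(
      "no baseline available for subject(s): %s",
      paste(unique(scored$subject_id[is.na(scored$baseline_bm_kg)]), collapse = ", ")
    ), class = "wutdiag_baseline_error")
  }
  scored %>%
    mutate(
      bml_loss_pct = compute_bml(.data$body_mass_kg, .data$baseline_bm_kg),
      w_met = .data$bml_loss_pct > thresholds$bml_loss_pct,
      u_met = .data$u_col >= thresholds$u_col,
      t_met = .data$thirst >= thresholds$thirst,
      wut_count = as.integer(.data$w_met) + as.integer(.data$u_met) +
        as.integer(.data$t_met),
      label = wut_labels[.data$wut_count + 1L],
      interpretation = unname(wut_interpretations[.data$label])
    ) %>%
    select(all_of(VISIT_KEY), "bml_loss_pct", "w_met", "u_met", "t_met",
           "wut_count", "label", "interpretation")
}
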
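#' Configuration for the synthetic hydration cohort
#'
#' Defines the design geometry (subjects x conditions x days x timepoints),
#' the latent dehydration mechanism and the marker observation model used by
#' [simulate_cohort()]. Defaults reproduce the emulated study design: 24
#' participants (half men, half women), free-living (FL) then euhydrated
#' (EUH) conditions, 3 consecutive days, first-morning and afternoon spot
#' samples — 288 visits in total — and 17 plasma samples missing in a
#' 6/4/4/3 split across the EUH-morning, EUH-afternoon, FL-morning and
#' FL-afternoon strata.
#'
#' The generative model draws, per visit, a latent binary dehydration state
#' `D` from `p_dehydrated[condition, timepoint]`, then a latent fluid
#' deficit `z = latent_deficit_scale * D + N(0, latent_noise_sd)`. Markers
#' are monotone linear maps of `z` plus Gaussian noise: body mass decreases
#' with `z` relative to the subject's true baseline mass (by
#' `marker_effect["body_mass"]` percent per unit `z`), while urine colour,
#' thirst, urine specific gravity, urine and plasma osmolality increase
#' (`marker_baseline + marker_effect * z`). Discrete markers are rounded
#' and clipped to their instrument scales. Euhydrated-condition visits are
#' rejection-sampled until the urine specific gravity screen (`usg < 1.020`)
#' is satisfied, mirroring how euhydration was enforced at enrolment rather
#' than by shifting distributions.
#'
#' @param n_subjects number of participants (split M/F as evenly as possible).
#' @param n_days consecutive study days per condition.
#' @param conditions ordered condition labels; subset of `c("FL", "EUH")`.
#' @param timepoints ordered timepoint labels; subset of
#'   `c("morning", "afternoon")`.
#' @param baseline_bm_mean_kg,baseline_bm_sd_kg named numeric (`M`, `F`):
#'   mean and SD of true baseline body mass per sex, in kg.
#' @param p_dehydrated named list `condition -> timepoint -> probability`
#'   of the latent dehydrated state.
#' @param latent_deficit_scale effect size coupling the latent state to the
#'   deficit `z` (unitless; 0 disables the signal).
#' @param latent_noise_sd SD of the Gaussian deficit noise.
#' @param marker_baseline named numeric: marker value at `z = 0`
#'   (`u_col`, `thirst`, `usg`, `u_osm`, `p_osm`).
#' @param marker_effect named numeric: change per unit `z` for each marker;
#'   `body_mass` is the percent of baseline mass lost per unit `z`.
#' @param marker_noise_sd named numeric: per-marker Gaussian observation
#'   noise SD (`body_mass` in kg).
#' @param missing_plasma named integer: plasma samples to drop per
#'   `condition.timepoint` stratum.
#' @param rng_seed integer seed making the cohort reproducible.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [inject_missingness()]
#' @examples
#' cfg <- sim_config(rng_seed = 1)
#' nrow(simulate_cohort(cfg))  # 288
#' @export
sim_config <- function(n_subjects = 24L,
                       n_days = 3L,
                       conditions = c("FL", "EUH"),
                       timepoints = c("morning", "afternoon"),
                       baseline_bm_mean_kg = c(M = 81.0, F = 68.8),
                       baseline_bm_sd_kg = c(M = 15.9, F = 15.2),
                       p_dehydrated = list(
                         FL = c(morning = 0.50, afternoon = 0.40),
                         EUH = c(morning = 0.05, afternoon = 0.10)
                       ),
                       latent_deficit_scale = 1.0,
                       latent_noise_sd = 0.25,
                       marker_baseline = c(
                         u_col = 2.0, thirst = 2.5, usg = 1.010,
                         u_osm = 400, p_osm = 285
                       ),
                       marker_effect = c(
                         body_mass = 1.5, u_col = 3.5, thirst = 3.5,
                         usg = 0.012, u_osm = 350, p_osm = 7
                       ),
                       marker_noise_sd = c(
                         body_mass = 0.15, u_col = 0.7, thirst = 0.8,
                         usg = 0.004, u_osm = 80, p_osm = 3
                       ),
                       missing_plasma = c(
                         EUH.morning = 6L, EUH.afternoon = 4L,
                         FL.morning = 4L, FL.afternoon = 3L
                       ),
                       rng_seed = 1L) {
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_days = as.integer(n_days),
      conditions = conditions,
      timepoints = timepoints,
      baseline_bm_mean_kg = baseline_bm_mean_kg,
      baseline_bm_sd_kg = baseline_bm_sd_kg,
      p_dehydrated = p_dehydrated,
      latent_deficit_scale = latent_deficit_scale,
      latent_noise_sd = latent_noise_sd,
      marker_baseline = marker_baseline,
      marker_effect = marker_effect,
      marker_noise_sd = marker_noise_sd,
      missing_plasma = missing_plasma,
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    abort(sprintf("invalid sim_config field `%s`: %s", field, msg),
          class = "wutdiag_config_error")
  }
  if (length(cfg$n_subjects) != 1 || is.na(cfg$n_subjects) || cfg$n_subjects < 1)
    fail("n_subjects", "must be a single count > 0")
  if (length(cfg$n_days) != 1 || is.na(cfg$n_days) || cfg$n_days < 1)
    fail("n_days", "must be a single count > 0")
  if (!length(cfg$conditions) || !all(cfg$conditions %in% c("FL", "EUH")) ||
      anyDuplicated(cfg$conditions))
    fail("conditions", "must be a non-empty subset of {FL, EUH} without duplicates")
  if (!length(cfg$timepoints) || !all(cfg$timepoints %in% c("morning", "afternoon")) ||
      anyDuplicated(cfg$timepoints))
    fail("timepoints", "must be a non-empty subset of {morning, afternoon} without duplicates")
  for (f in c("baseline_bm_mean_kg", "baseline_bm_sd_kg")) {
    v <- cfg[[f]]
    if (!all(c("M", "F") %in% names(v)) || any(!is.finite(v)) || any(v < 0))
      fail(f, "must be finite, non-negative and named M and F")
  }
  for (cond in cfg$conditions) {
    p <- cfg$p_dehydrated[[cond]]
    if (is.null(p) || !all(cfg$timepoints %in% names(p)))
      fail("p_dehydrated", sprintf("missing probabilities for condition %s", cond))
    if (any(p < 0 | p > 1, na.rm = FALSE) || any(!is.finite(p)))
      fail("p_dehydrated", "probabilities must lie in [0, 1]")
  }
  if (!is.finite(cfg$latent_deficit_scale))
    fail("latent_deficit_scale", "must be finite")
  if (!is.finite(cfg$latent_noise_sd) || cfg$latent_noise_sd < 0)
    fail("latent_noise_sd", "must be a non-negative number")
  need_base <- c("u_col", "thirst", "usg", "u_osm", "p_osm")
  if (!all(need_base %in% names(cfg$marker_baseline)))
    fail("marker_baseline", paste("must name", paste(need_base, collapse = ", ")))
  if (!all(MARKER_NAMES %in% names(cfg$marker_effect)))
    fail("marker_effect", paste("must name", paste(MARKER_NAMES, collapse = ", ")))
  if (!all(MARKER_NAMES %in% names(cfg$marker_noise_sd)))
    fail("marker_noise_sd", paste("must name", paste(MARKER_NAMES, collapse = ", ")))
  if (any(!is.finite(cfg$marker_noise_sd)) || any(cfg$marker_noise_sd < 0))
    fail("marker_noise_sd", "noise SDs must be non-negative")
  miss <- cfg$missing_plasma
  if (any(miss < 0) || any(!is.finite(miss)))
    fail("missing_plasma", "per-stratum counts must be non-negative")
  n_total <- cfg$n_subjects * length(cfg$conditions) * cfg$n_days * length(cfg$timepoints)
  if (sum(miss) > n_total)
    fail("missing_plasma", "total missing count exceeds total number of visits")
  if (length(cfg$rng_seed) != 1 || is.na(cfg$rng_seed))
    fail("rng_seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  n_total <- x$n_subjects * length(x$conditions) * x$n_days * length(x$timepoints)
  cat(sprintf(
    "<sim_config> %d subjects x %d conditions x %d days x %d timepoints = %d visits\n",
    x$n_subjects, length(x$conditions), x$n_days, length(x$timepoints), n_total
  ))
  cat(sprintf("  latent deficit scale %.3g (noise SD %.3g), seed %d\n",
              x$latent_deficit_scale, x$latent_noise_sd, x$rng_seed))
  cat(sprintf("  plasma samples to drop: %s\n",
              paste(names(x$missing_plasma), x$missing_plasma,
                    sep = "=", collapse = ", ")))
  invisible(x)
}
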
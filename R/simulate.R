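#' Simulate a synthetic hydration cohort
#'
#' Generates one visit record per (subject, condition, day, timepoint) cell
#' of the design described by a [sim_config()]: a latent binary dehydration
#' state per visit drives a latent fluid deficit, which in turn drives all
#' six hydration markers through monotone maps with Gaussian noise (see
#' [sim_config()] for the model). Euhydrated-condition visits are
#' rejection-sampled until they pass the urine specific gravity screen
#' (`usg < 1.020`), so the euhydrated/free-living contrast arises
#' structurally rather than from shifted distributions.
#'
#' Output precision follows the instruments being emulated: body mass to
#' 0.01 kg, urine specific gravity to 3 decimals, osmolalities to whole
#' mOsm/kg, urine colour and thirst as integers on their charts.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$rng_seed`. The same config
#'   and seed always reproduce the identical cohort.
#' @return a tibble with one row per visit: `subject_id`, `sex`,
#'   `condition`, `day`, `timepoint`, `body_mass_kg`, `u_col`, `thirst`,
#'   `usg`, `u_osm`, `p_osm`, and the latent truth flag
#'   `latent_dehydrated`. The subjects' true (noise-free) baseline masses
#'   are attached as the `true_baseline` attribute.
#' @examples
#' visits <- simulate_cohort(sim_config(rng_seed = 42))
#' table(visits$condition, visits$timepoint)
#' @export
simulate_cohort <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(as.integer(seed))

  n_m <- ceiling(config$n_subjects / 2)
  subjects <- tibble(
    subject_id = sprintf("S%02d", seq_len(config$n_subjects)),
    sex = rep(c("M", "F"), c(n_m, config$n_subjects - n_m))
  )
  subjects$true_baseline_kg <- draw_baseline_mass(subjects$sex, config)

  grid <- expand.grid(
    timepoint = config$timepoints,
    day = seq_len(config$n_days),
    condition = config$conditions,
    subject_id = subjects$subject_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("subject_id", "condition", "day", "timepoint")]
  grid <- as_tibble(grid)[order(match(grid$subject_id, subjects$subject_id),
                                match(grid$condition, config$conditions),
                                grid$day,
                                match(grid$timepoint, config$timepoints)), ]
  grid <- inner_join(grid, subjects, by = "subject_id")

  draws <- draw_markers(grid, config)

  # enforce the euhydration screen: EUH spot samples must show usg < 1.020
  redo <- which(grid$condition == "EUH" & draws$usg >= 1.020)
  tries <- 0L
  while (length(redo) > 0) {
    tries <- tries + 1L
    if (tries > 10000L) {
      abort(paste(
        "rejection sampling for the euhydration screen (usg < 1.020) did",
        "not converge; the configured usg baseline/noise makes euhydrated",
        "samples (near-)impossible"
      ), class = "wutdiag_sim_error")
    }
    redraw <- draw_markers(grid[redo, , drop = FALSE], config)
    ok <- redraw$usg < 1.020
    draws[redo[ok], ] <- redraw[ok, , drop = FALSE]
    redo <- redo[!ok]
  }

  out <- dplyr::bind_cols(
    grid[, c("subject_id", "sex", "condition", "day", "timepoint")],
    draws
  )
  out$day <- as.integer(out$day)
  attr(out, "true_baseline") <-
    subjects[, c("subject_id", "sex", "true_baseline_kg")]
  out
}

# truncated-normal baseline mass per sex (redraw below 40 kg)
draw_baseline_mass <- function(sex, config) {
  mu <- config$baseline_bm_mean_kg[sex]
  sd <- config$baseline_bm_sd_kg[sex]
  bm <- rnorm(length(sex), mu, sd)
  while (any(bad <- bm < 40)) bm[bad] <- rnorm(sum(bad), mu[bad], sd[bad])
  unname(bm)
}

# one stochastic draw of latent state + all six markers for each row of grid
draw_markers <- function(grid, config) {
  n <- nrow(grid)
  p <- vapply(seq_len(n), function(i) {
    config$p_dehydrated[[grid$condition[i]]][[grid$timepoint[i]]]
  }, numeric(1))
  d <- rbinom(n, 1L, p)
  z <- config$latent_deficit_scale * d + rnorm(n, 0, config$latent_noise_sd)

  base <- config$marker_baseline
  eff <- config$marker_effect
  nsd <- config$marker_noise_sd

  bml_frac <- (eff[["body_mass"]] / 100) * z
  tibble(
    body_mass_kg = round(
      grid$true_baseline_kg * (1 - bml_frac) + rnorm(n, 0, nsd[["body_mass"]]), 2),
    u_col = as.integer(clip(round(
      base[["u_col"]] + eff[["u_col"]] * z + rnorm(n, 0, nsd[["u_col"]])), 1, 8)),
    thirst = as.integer(clip(round(
      base[["thirst"]] + eff[["thirst"]] * z + rnorm(n, 0, nsd[["thirst"]])), 1, 9)),
    usg = clip(round(
      base[["usg"]] + eff[["usg"]] * z + rnorm(n, 0, nsd[["usg"]]), 3), 1.000, 1.040),
    u_osm = clip(round(
      base[["u_osm"]] + eff[["u_osm"]] * z + rnorm(n, 0, nsd[["u_osm"]])), 50, 1400),
    p_osm = clip(round(
      base[["p_osm"]] + eff[["p_osm"]] * z + rnorm(n, 0, nsd[["p_osm"]])), 250, 340),
    latent_dehydrated = d == 1L
  )
}

#' Drop plasma osmolality values by stratum
#'
#' Marks `p_osm` as missing (`NA`) for a configured number of visits in each
#' (condition, timepoint) stratum, selected uniformly at random within the
#' stratum, emulating plasma samples lost to technical issues. All other
#' fields are untouched. With the default configuration this removes
#' 6 + 4 + 4 + 3 = 17 of the 288 plasma values, leaving 271.
#'
#' @param records visit tibble from [simulate_cohort()] (or any table with
#'   `condition`, `timepoint` and `p_osm` columns).
#' @param config a [sim_config()]; `config$missing_plasma` gives the
#'   per-stratum counts, named `condition.timepoint`.
#' @param seed integer seed for the uniform selection; defaults to
#'   `config$rng_seed`.
#' @return `records` with the sampled `p_osm` entries set to `NA`.
#' @examples
#' cfg <- sim_config(rng_seed = 7)
#' visits <- inject_missingness(simulate_cohort(cfg), cfg)
#' sum(!is.na(visits$p_osm))  # 271 under the default design
#' @export
inject_missingness <- function(records, config, seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$missing_plasma
  if (!length(counts) || sum(counts) == 0) return(records)
  set.seed(as.integer(seed))
  stratum <- paste(records$condition, records$timepoint, sep = ".")
  for (s in names(counts)) {
    k <- counts[[s]]
    if (k == 0) next
    idx <- which(stratum == s)
    if (k > length(idx)) {
      abort(sprintf(
        "missing_plasma[%s] = %d exceeds the %d visits in that stratum",
        s, k, length(idx)
      ), class = "wutdiag_sim_error")
    }
    drop <- if (length(idx) == 1) idx else sample(idx, k)
    records$p_osm[drop] <- NA_real_
  }
  records
}
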
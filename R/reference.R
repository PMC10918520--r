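#' Reference-standard dehydration thresholds
#'
#' Laboratory criteria indicating dehydration: urine specific gravity at or
#' above 1.020, urine osmolality strictly above 700 mOsm/kg, plasma
#' osmolality strictly above 290 mOsm/kg. The urine specific gravity
#' comparator is inclusive by default — consistent with the euhydration
#' screen (`usg < 1.020`) partitioning the scale — but can be set strict to
#' reproduce the alternative convention.
#'
#' @param usg urine specific gravity threshold (default 1.020).
#' @param u_osm urine osmolality threshold, mOsm/kg (default 700, strict >).
#' @param p_osm plasma osmolality threshold, mOsm/kg (default 290, strict >).
#' @param usg_comparator `">="` (default) or `">"`.
#' @return a `reference_thresholds` list.
#' @export
reference_thresholds <- function(usg = 1.020, u_osm = 700, p_osm = 290,
                                 usg_comparator = c(">=", ">")) {
  usg_comparator <- match.arg(usg_comparator)
  if (!is.finite(usg) || usg <= 1.000)
    abort("invalid threshold `usg`: must exceed 1.000")
  if (!is.finite(u_osm) || u_osm <= 0)
    abort("invalid threshold `u_osm`: must be positive")
  if (!is.finite(p_osm) || p_osm <= 0)
    abort("invalid threshold `p_osm`: must be positive")
  structure(list(usg = usg, u_osm = u_osm, p_osm = p_osm,
                 usg_comparator = usg_comparator),
            class = "reference_thresholds")
}

ref_marker_column <- c(USG = "usg", UOSM = "u_osm", POSM = "p_osm")

#' Binary reference calls per visit and marker
#'
#' Applies the reference-standard thresholds to each visit, one call per
#' requested marker. A missing measurement (plasma osmolality only, in the
#' emulated design) propagates to a missing call — never a guess.
#'
#' @param records visit table with the visit key and `usg`, `u_osm`,
#'   `p_osm` columns.
#' @param thresholds a [reference_thresholds()].
#' @param markers subset of `c("USG", "UOSM", "POSM")`.
#' @return long tibble: visit key columns, `marker`, `value`, `dehydrated`
#'   (logical; `NA` when the measurement is missing).
#' @examples
#' visits <- simulate_cohort(sim_config(rng_seed = 1))
#' calls <- classify_reference(visits)
#' table(calls$marker, calls$dehydrated, useNA = "ifany")
#' @export
classify_reference <- function(records, thresholds = reference_thresholds(),
                               markers = REF_MARKERS) {
  stopifnot(inherits(thresholds, "reference_thresholds"))
  unknown <- setdiff(markers, REF_MARKERS)
  if (length(unknown))
    abort(sprintf("unknown reference marker(s): %s (expected %s)",
                  paste(unknown, collapse = ", "),
                  paste(REF_MARKERS, collapse = ", ")),
          class = "wutdiag_input_error")
  usg_met <- if (thresholds$usg_comparator == ">=") {
    function(x) x >= thresholds$usg
  } else {
    function(x) x > thresholds$usg
  }
  one_marker <- function(marker) {
    value <- records[[ref_marker_column[[marker]]]]
    dehydrated <- switch(marker,
      USG = usg_met(value),
      UOSM = value > thresholds$u_osm,
      POSM = value > thresholds$p_osm
    )
    dplyr::bind_cols(
      records[, VISIT_KEY],
      tibble(marker = marker, value = value, dehydrated = dehydrated)
    )
  }
  bind_rows(lapply(markers, one_marker))
}
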
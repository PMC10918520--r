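#' Write a visit table to CSV
#'
#' RFC 4180 CSV, UTF-8, '.' decimal; missing plasma osmolality is encoded
#' as an empty field. The latent truth column is suppressed by default so
#' downstream scoring can be run blinded.
#'
#' @param records visit tibble (from [simulate_cohort()] or compatible).
#' @param path output file.
#' @param with_truth keep the `latent_dehydrated` column? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_visits <- function(records, path, with_truth = FALSE) {
  if (!with_truth) records$latent_dehydrated <- NULL
  readr::write_csv(records, path, na = "")
  invisible(path)
}

visit_col_types <- readr::cols(
  subject_id = readr::col_character(),
  sex = readr::col_character(),
  condition = readr::col_character(),
  day = readr::col_integer(),
  timepoint = readr::col_character(),
  body_mass_kg = readr::col_double(),
  u_col = readr::col_integer(),
  thirst = readr::col_integer(),
  usg = readr::col_double(),
  u_osm = readr::col_double(),
  p_osm = readr::col_double(),
  latent_dehydrated = readr::col_logical()
)

#' Read and validate a visit CSV
#'
#' Reads the long-format per-visit schema written by [write_visits()],
#' enforcing types and marker ranges. Violations are reported with their
#' row numbers. An empty `p_osm` cell becomes a missing value; every other
#' measurement column is mandatory and must be populated.
#'
#' @param path CSV file with columns `subject_id`, `sex`, `condition`,
#'   `day`, `timepoint`, `body_mass_kg`, `u_col`, `thirst`, `usg`,
#'   `u_osm`, `p_osm` (and optionally `latent_dehydrated`).
#' @return a typed visit tibble.
#' @export
read_visits <- function(path) {
  if (!file.exists(path))
    abort(sprintf("visit file not found: %s", path), class = "wutdiag_io_error")
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  mandatory <- c("subject_id", "sex", "condition", "day", "timepoint",
                 "body_mass_kg", "u_col", "thirst", "usg", "u_osm", "p_osm")
  missing_cols <- setdiff(mandatory, header)
  if (length(missing_cols))
    abort(sprintf("missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "wutdiag_io_error")

  keep <- visit_col_types
  keep$cols <- keep$cols[intersect(names(keep$cols), header)]
  visits <- readr::read_csv(path, col_types = keep, na = c("", "NA"),
                            show_col_types = FALSE)
  validate_visits(visits)
  visits
}

validate_visits <- function(visits) {
  problems <- character()
  note <- function(bad, field, msg) {
    rows <- which(bad)
    if (length(rows)) {
      problems <<- c(problems, sprintf(
        "%s %s at row(s) %s", field, msg,
        paste(utils::head(rows, 5), collapse = ", ")
      ))
    }
  }
  isna_or <- function(x, test) !is.na(x) & test
  note(is.na(visits$subject_id), "subject_id", "is missing")
  note(isna_or(visits$sex, !(visits$sex %in% c("M", "F"))), "sex",
       "must be M or F")
  note(isna_or(visits$condition, !(visits$condition %in% c("FL", "EUH"))),
       "condition", "must be FL or EUH")
  note(isna_or(visits$timepoint,
               !(visits$timepoint %in% c("morning", "afternoon"))),
       "timepoint", "must be morning or afternoon")
  note(is.na(visits$day) | visits$day < 1, "day", "must be a positive index")
  note(is.na(visits$body_mass_kg) | visits$body_mass_kg <= 0,
       "body_mass_kg", "must be positive")
  note(is.na(visits$u_col) | visits$u_col < 1 | visits$u_col > 8,
       "u_col", "must lie on the 1-8 colour chart")
  note(is.na(visits$thirst) | visits$thirst < 1 | visits$thirst > 9,
       "thirst", "must lie on the 1-9 scale")
  note(is.na(visits$usg) | visits$usg < 1, "usg", "must be >= 1.000")
  note(is.na(visits$u_osm) | visits$u_osm <= 0, "u_osm", "must be positive")
  note(isna_or(visits$p_osm, visits$p_osm <= 0), "p_osm",
       "must be positive when present")
  dup <- duplicated(visits[, VISIT_KEY])
  note(dup, "visit key", "duplicates an earlier (subject, condition, day, timepoint)")
  if (length(problems))
    abort(paste0("invalid visit records:\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "wutdiag_io_error")
  invisible(visits)
}

#' Count visits per WUT category and stratum
#'
#' Tabulates the scored visits into the WUT0-WUT3 categories, one row per
#' stratum (by default crossing timepoint with condition), with row sums
#' equal to the number of scored visits.
#'
#' @param wut_results scored visits from [score_wut()].
#' @param by stratifying columns (default `c("timepoint", "condition")`);
#'   use `character(0)` for a single pooled row.
#' @return tibble with the `by` columns, `WUT0`..`WUT3` counts and `total`.
#' @export
wut_category_table <- function(wut_results, by = c("timepoint", "condition")) {
  wut_results$label <- factor(wut_results$label, levels = wut_labels)
  counts <- wut_results %>%
    group_by(across(all_of(by)), .data$label, .drop = FALSE) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (lab in wut_labels) if (!lab %in% names(counts)) counts[[lab]] <- 0L
  counts$total <- rowSums(counts[, wut_labels])
  counts %>% arrange(across(all_of(by)))
}

fmt_metric <- function(value, reason) {
  ifelse(is.na(value),
         sprintf("NA (%s)", ifelse(is.na(reason), "undefined", reason)),
         sprintf("%.3f", value))
}

#' Render the accuracy report
#'
#' Produces a deterministic plain-text report in the shape of the study's
#' summary tables: WUT category counts per stratum, then per-stratum
#' sensitivity / specificity / cut-off determination value / PPV / NPV for
#' every marker and WUT threshold, with `*` marking values that pass the
#' practical-significance rule (greater than both the cut-off value and the
#' flag threshold). Values are rounded to 3 decimals for display only; the
#' full-precision numbers live in the metrics tibble.
#'
#' @param metrics output of [evaluate_accuracy()].
#' @param category_table output of [wut_category_table()].
#' @param meta optional named character vector echoed as provenance lines
#'   (e.g. seed, config hash).
#' @return character vector of report lines.
#' @export
render_report <- function(metrics, category_table, meta = NULL) {
  lines <- c("WUT Venn diagram diagnostic accuracy report",
             strrep("=", 43))
  if (!is.null(meta))
    lines <- c(lines, sprintf("meta: %s = %s", names(meta), unname(meta)), "")

  lines <- c(lines, "", "WUT category counts", strrep("-", 19))
  by <- setdiff(names(category_table), c(wut_labels, "total"))
  for (i in seq_len(nrow(category_table))) {
    stratum <- if (length(by)) {
      paste(paste(by, unlist(category_table[i, by]), sep = "="), collapse = ", ")
    } else "pooled"
    lines <- c(lines, sprintf(
      "%s: WUT0=%d WUT1=%d WUT2=%d WUT3=%d (total %d)",
      stratum, category_table$WUT0[i], category_table$WUT1[i],
      category_table$WUT2[i], category_table$WUT3[i], category_table$total[i]
    ))
  }

  metrics <- metrics %>%
    arrange(match(.data$marker, REF_MARKERS),
            match(.data$timepoint, c("morning", "afternoon", "both")),
            match(.data$condition, c("EUH", "FL", "both")),
            .data$k)
  strata <- distinct(metrics[, c("timepoint", "condition")])
  for (i in seq_len(nrow(strata))) {
    tp <- strata$timepoint[i]; cond <- strata$condition[i]
    lines <- c(lines, "", sprintf("Stratum: timepoint=%s, condition=%s", tp, cond),
               strrep("-", 40))
    sub <- metrics[metrics$timepoint == tp & metrics$condition == cond, ]
    for (j in seq_len(nrow(sub))) {
      r <- sub[j, ]
      lines <- c(lines, sprintf(
        "%-4s WUT>=%d  sens %s%s  spec %s%s  ppv %s  npv %s  cutoff(%s) %s [k=%s]",
        r$marker, r$k,
        fmt_metric(r$sensitivity, r$sensitivity_reason),
        ifelse(isTRUE(r$flag_sensitivity), "*", " "),
        fmt_metric(r$specificity, r$specificity_reason),
        ifelse(isTRUE(r$flag_specificity), "*", " "),
        fmt_metric(r$ppv, r$ppv_reason),
        fmt_metric(r$npv, r$npv_reason),
        r$criterion,
        ifelse(is.na(r$cutoff_value), "NA", sprintf("%.3f", r$cutoff_value)),
        ifelse(is.na(r$cutoff_k), "NA", as.character(r$cutoff_k))
      ))
    }
  }
  lines <- c(lines,
             "",
             "* sensitivity/specificity > cut-off determination value and > flag threshold")
  lines
}

#' Write a rendered report to disk
#'
#' @param lines character vector from [render_report()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_report <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}
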
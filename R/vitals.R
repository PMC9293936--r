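# Preprocessing of ICP / MAP pressure series: minute rounding, extreme-value
# exclusion, CPP derivation, horizon truncation and cohort eligibility.
#
# All time is integer minutes since ICU admission (t = 0); every window in the
# package is half-open [a, b) in minutes.

#' Physiological plausibility limits for pressure signals
#'
#' Exclusion thresholds for raw ICP and MAP samples. Values strictly outside
#' the limits are treated as monitor artifacts and removed; boundary values
#' are retained (the inequalities are strict).
#'
#' @return Named list with elements `icp = c(0, 100)` and `map = c(20, 150)`,
#'   in mmHg.
#' @export
pressure_limits <- function() {
  list(icp = c(lower = 0, upper = 100), map = c(lower = 20, upper = 150))
}

#' Round raw sample times to the minute grid and collapse duplicates
#'
#' Monitors export 1-5-minute median values with second-resolution
#' timestamps. This snaps each sample to the nearest whole minute (ties round
#' half up) and collapses samples landing on the same minute to their median,
#' so each (patient, signal) series is strictly increasing in `time_min` with
#' at most one value per minute. Gaps are left as gaps: nothing is imputed.
#'
#' @param raw A data frame with columns `time_s` (seconds since admission)
#'   and `value` (mmHg). Optional `patient_id` and `signal` columns are used
#'   as grouping keys and carried through.
#' @return A tibble with columns (`patient_id`, `signal`,) `time_min`,
#'   `value`, sorted by time within group.
#' @examples
#' round_and_deduplicate(data.frame(time_s = c(60, 61, 90), value = c(10, 20, 15)))
#' @export
round_and_deduplicate <- function(raw) {
  assert_columns(raw, c("time_s", "value"), "raw vitals")
  keys <- intersect(c("patient_id", "signal"), names(raw))
  if (nrow(raw) == 0) {
    out <- as_tibble(raw[0, keys, drop = FALSE])
    out$time_min <- integer()
    out$value <- double()
    return(out)
  }
  if (any(!is.finite(raw$value))) {
    stop_icpdyn("raw vitals contain non-finite values", "icpdyn_data_error")
  }
  raw |>
    mutate(time_min = as.integer(floor(.data$time_s / 60 + 0.5))) |>
    group_by(across(dplyr::all_of(c(keys, "time_min")))) |>
    summarise(value = stats::median(.data$value), .groups = "drop") |>
    arrange(across(dplyr::all_of(c(keys, "time_min"))))
}

#' Remove physiologically impossible pressure values
#'
#' Drops ICP samples outside (0, 100) violations — i.e. ICP > 100 or ICP < 0
#' mmHg — and MAP samples with MAP > 150 or MAP < 20 mmHg. Inequalities are
#' strict: boundary values (ICP = 0 or 100, MAP = 20 or 150) are kept.
#' CPP must never be passed through this filter; it is derived *after*
#' filtering and carries no range filter of its own.
#'
#' @param vitals Long tibble with columns `signal` (`"icp"`/`"map"`) and
#'   `value`; extra columns pass through.
#' @param limits Limits as returned by [pressure_limits()].
#' @param quiet Suppress the removal-count message.
#' @return The filtered tibble, with an `"excluded"` attribute holding a
#'   per-signal count of removed samples.
#' @export
exclude_extremes <- function(vitals, limits = pressure_limits(), quiet = FALSE) {
  assert_columns(vitals, c("signal", "value"), "vitals")
  sig <- normalise_signal(vitals$signal)
  if (any(sig == "cpp")) {
    stop_icpdyn(
      "exclude_extremes() must not be applied to CPP: CPP is derived from already-filtered MAP and ICP",
      "icpdyn_data_error"
    )
  }
  unknown <- setdiff(unique(sig), names(limits))
  if (length(unknown) > 0) {
    stop_icpdyn(paste0("no exclusion limits for signal(s): ",
                       paste(unknown, collapse = ", ")), "icpdyn_data_error")
  }
  lo <- vapply(limits, `[[`, numeric(1), "lower")[sig]
  hi <- vapply(limits, `[[`, numeric(1), "upper")[sig]
  keep <- vitals$value >= lo & vitals$value <= hi
  excluded <- table(factor(sig[!keep], levels = names(limits)))
  inform_counts("exclude_extremes: removed ", sum(!keep), " of ", nrow(vitals),
                " samples (",
                paste(sprintf("%s=%d", names(excluded), as.integer(excluded)),
                      collapse = ", "),
                ")", quiet = quiet)
  out <- vitals[keep, , drop = FALSE]
  attr(out, "excluded") <- as.integer(excluded) |> setNames(names(excluded))
  out
}

#' Derive cerebral perfusion pressure
#'
#' CPP is defined as MAP minus ICP. It is computed minute-wise on the
#' intersection of the two (already extreme-filtered) series: a minute present
#' in only one signal yields no CPP sample.
#'
#' @param vitals Long tibble with columns `time_min`, `signal`, `value`
#'   (and optionally `patient_id`). Must contain `icp` and `map` rows and no
#'   pre-existing `cpp` rows.
#' @return The input with derived `cpp` rows appended.
#' @export
derive_cpp <- function(vitals) {
  assert_columns(vitals, c("time_min", "signal", "value"), "vitals")
  vitals <- mutate(vitals, signal = normalise_signal(.data$signal))
  if (any(vitals$signal == "cpp")) {
    stop_icpdyn("input already contains cpp rows; CPP must be derived, not supplied",
                "icpdyn_data_error")
  }
  keys <- intersect("patient_id", names(vitals))
  icp <- filter(vitals, .data$signal == "icp")
  map <- filter(vitals, .data$signal == "map")
  cpp <- inner_join(
    select(map, dplyr::all_of(c(keys, "time_min")), map_value = "value"),
    select(icp, dplyr::all_of(c(keys, "time_min")), icp_value = "value"),
    by = c(keys, "time_min")
  ) |>
    mutate(signal = "cpp", value = .data$map_value - .data$icp_value) |>
    select(dplyr::all_of(c(keys, "time_min", "signal", "value")))
  bind_rows(vitals, cpp) |>
    arrange(across(dplyr::all_of(c(keys, "signal", "time_min"))))
}

#' Truncate vitals to the analysis horizon
#'
#' Drops every sample at or beyond `horizon_h` hours after admission
#' (half-open window `[0, horizon_h)` in minutes), the span over which the
#' dynamic model operates (default: the first 120 h of intensive care).
#'
#' @param vitals Long tibble with a `time_min` column.
#' @param horizon_h Horizon in hours (> 0); default 120.
#' @return The truncated tibble.
#' @export
truncate_to_horizon <- function(vitals, horizon_h = 120) {
  assert_columns(vitals, "time_min", "vitals")
  stopifnot(is.numeric(horizon_h), length(horizon_h) == 1, horizon_h > 0)
  filter(vitals, .data$time_min < horizon_h * 60)
}

#' Cohort eligibility for dynamic prediction
#'
#' A patient enters the cohort when they are an adult (age >= 16 years) and
#' have ICP monitoring spanning at least 24 h. "At least 24 h" is read as
#' monitoring *span* — the last ICP sample falls at minute >= `min_span_h*60`
#' — not a count of samples; `rule = "cumulative"` instead sums inter-sample
#' gaps capped at 5 minutes (the coarsest storage resolution), and
#' `min_coverage` optionally requires a minimum fraction of minutes within
#' the span to carry an ICP sample (default 0: no density requirement).
#'
#' @param vitals Long tibble with `patient_id`, `time_min`, `signal`.
#' @param metadata Tibble with `patient_id`, `age_years`.
#' @param min_age Minimum age in years (default 16).
#' @param min_span_h Minimum ICP monitoring extent in hours (default 24).
#' @param min_coverage Minimum fraction of minutes in `[0, span]` with an ICP
#'   sample; default 0.
#' @param rule `"span"` (default) or `"cumulative"`.
#' @return `metadata` with logical column `eligible` plus the diagnostics
#'   used (`icp_span_h`, `icp_coverage`).
#' @export
is_eligible <- function(vitals, metadata, min_age = 16, min_span_h = 24,
                        min_coverage = 0, rule = c("span", "cumulative")) {
  rule <- match.arg(rule)
  assert_columns(vitals, c("patient_id", "time_min", "signal"), "vitals")
  assert_columns(metadata, c("patient_id", "age_years"), "metadata")
  icp <- vitals |>
    filter(normalise_signal(.data$signal) == "icp") |>
    group_by(.data$patient_id) |>
    summarise(
      icp_span_h = max(.data$time_min) / 60,
      icp_cum_h = sum(pmin(diff(sort(unique(.data$time_min))), 5)) / 60,
      icp_coverage = n_distinct(.data$time_min) / (max(.data$time_min) + 1),
      .groups = "drop"
    )
  metadata |>
    left_join(icp, by = "patient_id") |>
    mutate(
      icp_span_h = dplyr::coalesce(.data$icp_span_h, 0),
      icp_cum_h = dplyr::coalesce(.data$icp_cum_h, 0),
      icp_coverage = dplyr::coalesce(.data$icp_coverage, 0),
      eligible = .data$age_years >= min_age &
        (if (rule == "span") .data$icp_span_h >= min_span_h
         else .data$icp_cum_h >= min_span_h) &
        .data$icp_coverage >= min_coverage
    )
}

#' Read a long-format vitals CSV
#'
#' Expected header: `patient_id,time_min,signal,value` with
#' `signal` in `{ICP, MAP}` (case-insensitive). CPP rows in input are dropped
#' with a warning, because CPP is always derived after filtering.
#'
#' @param path CSV path.
#' @param quiet Suppress the row-count message.
#' @return Tibble `patient_id, time_min, signal, value` with lowercase
#'   signal names.
#' @export
read_vitals <- function(path, quiet = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("patient_id", "time_min", "signal", "value"),
                 sprintf("vitals file '%s'", path))
  df <- mutate(df,
               patient_id = as.character(.data$patient_id),
               time_min = as.integer(.data$time_min),
               signal = normalise_signal(.data$signal))
  if (any(df$signal == "cpp")) {
    n_cpp <- sum(df$signal == "cpp")
    rlang::warn(sprintf(
      "%s: ignoring %d CPP rows (CPP is derived from filtered MAP and ICP, never read)",
      path, n_cpp))
    df <- filter(df, .data$signal != "cpp")
  }
  bad <- setdiff(unique(df$signal), c("icp", "map"))
  if (length(bad) > 0) {
    stop_icpdyn(sprintf("%s: unknown signal(s): %s", path,
                        paste(bad, collapse = ", ")), "icpdyn_data_error")
  }
  inform_counts("read_vitals: ", nrow(df), " samples, ",
                n_distinct(df$patient_id), " patients from ", path,
                quiet = quiet)
  df
}

#' Read a cohort metadata CSV
#'
#' Expected header: `patient_id,age_years,outcome[,admission_iso8601]`;
#' `outcome` is 1 for death within 30 days of admission, 0 for survival.
#'
#' @inheritParams read_vitals
#' @return Tibble with `patient_id`, `age_years`, `outcome` (integer 0/1)
#'   and, when present, `admission_iso8601`.
#' @export
read_cohort_metadata <- function(path, quiet = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("patient_id", "age_years", "outcome"),
                 sprintf("metadata file '%s'", path))
  df <- mutate(df,
               patient_id = as.character(.data$patient_id),
               age_years = as.numeric(.data$age_years),
               outcome = as.integer(.data$outcome))
  if (anyDuplicated(df$patient_id)) {
    stop_icpdyn(sprintf("%s: duplicated patient_id", path), "icpdyn_data_error")
  }
  if (!all(df$outcome %in% c(0L, 1L))) {
    stop_icpdyn(sprintf("%s: outcome must be 0/1", path), "icpdyn_data_error")
  }
  inform_counts("read_cohort_metadata: ", nrow(df), " patients from ", path,
                quiet = quiet)
  df
}

#' Assemble an analysis-ready cohort
#'
#' Runs the full preprocessing chain on raw minute-gridded vitals: horizon
#' truncation, extreme-value exclusion, CPP derivation and eligibility
#' marking. Nothing is imputed at any step.
#'
#' @param vitals Long tibble `patient_id, time_min, signal, value` with
#'   signals `icp`/`map` (e.g. from [read_vitals()]).
#' @param metadata Tibble from [read_cohort_metadata()].
#' @param horizon_h Analysis horizon in hours; default 120.
#' @param quiet Suppress count messages.
#' @inheritParams is_eligible
#' @return An object of class `icp_cohort`: a list with tibbles `vitals`
#'   (including derived `cpp`) and `patients` (metadata + `monitoring_end_min`
#'   + `eligible`), restricted to eligible patients.
#' @export
prepare_cohort <- function(vitals, metadata, horizon_h = 120, min_age = 16,
                           min_span_h = 24, min_coverage = 0,
                           rule = c("span", "cumulative"), quiet = FALSE) {
  rule <- match.arg(rule)
  vitals <- vitals |>
    mutate(signal = normalise_signal(.data$signal)) |>
    truncate_to_horizon(horizon_h) |>
    exclude_extremes(quiet = quiet) |>
    derive_cpp()
  elig <- is_eligible(vitals, metadata, min_age = min_age,
                      min_span_h = min_span_h, min_coverage = min_coverage,
                      rule = rule)
  inform_counts("prepare_cohort: ", sum(elig$eligible), " of ", nrow(elig),
                " patients eligible (age >= ", min_age, ", ICP ", rule,
                " >= ", min_span_h, " h)", quiet = quiet)
  end_min <- vitals |>
    group_by(.data$patient_id) |>
    summarise(monitoring_end_min = max(.data$time_min), .groups = "drop")
  patients <- elig |>
    filter(.data$eligible) |>
    left_join(end_min, by = "patient_id")
  structure(
    list(vitals = filter(vitals, .data$patient_id %in% patients$patient_id),
         patients = patients),
    class = "icp_cohort"
  )
}

#' @export
print.icp_cohort <- function(x, ...) {
  cat(sprintf(
    "<icp_cohort> %d patients, %d samples (%s)\n  mortality %.1f%%, median age %.0f y, mean monitoring %.1f h\n",
    nrow(x$patients), nrow(x$vitals),
    paste(sort(unique(x$vitals$signal)), collapse = "/"),
    100 * mean(x$patients$outcome),
    stats::median(x$patients$age_years),
    mean(x$patients$monitoring_end_min) / 60))
  invisible(x)
}
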
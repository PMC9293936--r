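# Rolling-window feature engineering.
#
# Three aggregations per (signal, statistic):
#   begin — statistic over the first 24 h window [0, 1440) min
#   end   — statistic over the trailing 8 h window [(t-8)h, t h)
#   coef  — OLS slope of the statistic computed in 4-h rolling windows
#           (1-h stride, windows ending at whole hours 4..t) against window
#           end time, i.e. the trend of the statistic up to prediction time t.
# Plus `agec`, age in decade bins.

#' Window statistic kinds
#'
#' The per-window statistics the feature grammar draws from. `avg` renders
#' as the plain signal name (`icp_end`, not `icp_avg_end`). `ht20`/`lt10`
#' (fraction of samples strictly above 20 / below 10 mmHg) are ICP-only;
#' `ht120` (fraction strictly above 120 mmHg, severe arterial hypertension)
#' is MAP-only. `min`/`max` are implemented but excluded from the default
#' candidate grammar.
#'
#' @return Character vector of statistic names.
#' @export
window_stat_kinds <- function() {
  c("avg", "min", "max", "diff", "var", "q90", "q10", "ht20", "lt10", "ht120")
}

stat_valid_for <- function(kind, signal) {
  if (kind %in% c("ht20", "lt10")) return(signal == "icp")
  if (kind == "ht120") return(signal == "map")
  TRUE
}

# All requested statistics of one window's values (already time-ordered).
# Empty window -> all NA; single sample -> diff and var NA, others defined.
compute_window_stats <- function(v, kinds) {
  out <- rep(NA_real_, length(kinds))
  names(out) <- kinds
  n <- length(v)
  if (n == 0L) return(out)
  for (i in seq_along(kinds)) {
    out[i] <- switch(kinds[i],
      avg = mean(v),
      min = min(v),
      max = max(v),
      diff = if (n >= 2L) mean(diff(v)) else NA_real_,
      var = if (n >= 2L) sum((v - mean(v))^2) / n else NA_real_,
      q90 = unname(stats::quantile(v, 0.90, names = FALSE, type = 7)),
      q10 = unname(stats::quantile(v, 0.10, names = FALSE, type = 7)),
      ht20 = mean(v > 20),
      lt10 = mean(v < 10),
      ht120 = mean(v > 120),
      stop_icpdyn(paste0("unknown window statistic: ", kinds[i]))
    )
  }
  out
}

#' Compute one statistic over a half-open time window
#'
#' Statistics are computed over the samples *present* in `[a_min, b_min)`
#' only; gaps are ignored, never imputed. `diff` is the mean of signed
#' consecutive differences of the in-window values ordered by time; `var` is
#' the population (1/n) variance; `q90`/`q10` use linear interpolation
#' between order statistics; `ht20`/`lt10`/`ht120` are fractions under strict
#' inequalities. An empty window gives `NA`; a single sample gives `NA` for
#' `diff` and `var` and a defined value otherwise.
#'
#' @param series Tibble with `time_min` and `value` (one patient, one signal),
#'   sorted by time.
#' @param a_min,b_min Window bounds in minutes, half-open `[a, b)`.
#' @param kind One of [window_stat_kinds()].
#' @param signal Optional signal name; when given, the kind/signal pairing is
#'   validated (`ht20`/`lt10` are ICP-only, `ht120` MAP-only).
#' @return A single numeric value or `NA`.
#' @export
window_stat <- function(series, a_min, b_min, kind, signal = NULL) {
  stopifnot(a_min < b_min)
  kind <- match.arg(kind, window_stat_kinds())
  if (!is.null(signal) && !stat_valid_for(kind, normalise_signal(signal))) {
    stop_icpdyn(sprintf("statistic '%s' is not defined for signal '%s'",
                        kind, signal))
  }
  v <- series$value[series$time_min >= a_min & series$time_min < b_min]
  unname(compute_window_stats(v, kind)[kind])
}

#' @rdname window_stat
#' @param t_h Prediction time in hours (>= 24).
#' @details `begin_feature()` is the statistic over the first 24 h
#'   (`[0, 1440)` min); `end_feature()` over the trailing 8 h
#'   (`[(t_h-8)*60, t_h*60)`); `coef_feature()` the OLS slope (stat units per
#'   hour) of the per-4-h-rolling-window statistic sequence against window end
#'   time, windows ending at whole hours 4..`t_h`, missing windows dropped,
#'   `NA` when fewer than two windows remain.
#' @export
begin_feature <- function(series, kind, signal = NULL) {
  window_stat(series, 0, 1440, kind, signal)
}

#' @rdname window_stat
#' @export
end_feature <- function(series, kind, t_h, signal = NULL) {
  stopifnot(t_h >= 24)
  window_stat(series, (t_h - 8) * 60, t_h * 60, kind, signal)
}

#' @rdname window_stat
#' @param width_h,stride_h Rolling-window width and stride in hours
#'   (defaults 4 and 1).
#' @export
coef_feature <- function(series, kind, t_h, signal = NULL,
                         width_h = 4, stride_h = 1) {
  stopifnot(t_h >= 24)
  ends <- seq(width_h, t_h, by = stride_h)
  y <- vapply(ends, function(k) {
    window_stat(series, (k - width_h) * 60, k * 60, kind, signal)
  }, numeric(1))
  ols_slope(ends, y)
}

# OLS slope of y on x with NA dropped; NA when < 2 points or x degenerate.
ols_slope <- function(x, y) {
  ok <- !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) return(NA_real_)
  sum(xc * (y - mean(y))) / sxx
}

#' Age in decade bins
#'
#' `floor(age / 10)` clipped to `[1, 9]`: 16 -> 1, 46 -> 4, 95 -> 9.
#'
#' @param age_years Numeric age(s) in years, >= 0.
#' @return Integer decile code(s).
#' @export
age_decile <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) {
    stop_icpdyn("age_years must be non-negative")
  }
  as.integer(pmin(pmax(floor(age_years / 10), 1), 9))
}

#' Feature grammar configuration
#'
#' Defines the candidate feature set as a cross of signals, per-window
#' statistics and aggregations. The default grammar is
#' \{icp, map, cpp\} x \{avg, diff, var, q90, q10\} x \{begin, end, coef\}
#' (45 features) plus the threshold-fraction features
#' \{icp_ht20, icp_lt10, map_ht120\} x \{begin, end, coef\} (9) and `agec`,
#' i.e. 54 signal features + age — 55 candidates. Setting
#' `include_minmax = TRUE` adds per-window min/max (73 candidates), flagged
#' as non-default.
#'
#' @param include_minmax Add `min`/`max` statistics to the grammar.
#' @param begin_h First-window length in hours (default 24).
#' @param end_h Trailing-window length in hours (default 8).
#' @param coef_width_h,coef_stride_h Rolling-window geometry for `coef`
#'   trends (defaults 4 and 1 h).
#' @param diff_absolute Use absolute instead of signed consecutive
#'   differences for `diff` (default `FALSE`: signed).
#' @param thresholds mmHg thresholds for `ht20`/`lt10`/`ht120`.
#' @return An object of class `icp_grammar`.
#' @export
feature_grammar <- function(include_minmax = FALSE, begin_h = 24, end_h = 8,
                            coef_width_h = 4, coef_stride_h = 1,
                            diff_absolute = FALSE,
                            thresholds = c(ht20 = 20, lt10 = 10, ht120 = 120)) {
  structure(
    list(
      signals = c("icp", "map", "cpp"),
      stats = c("avg", if (include_minmax) c("min", "max"),
                "diff", "var", "q90", "q10"),
      aggregations = c("begin", "end", "coef"),
      threshold_stats = list(icp = c("ht20", "lt10"), map = "ht120",
                             cpp = character()),
      include_minmax = include_minmax,
      begin_h = begin_h, end_h = end_h,
      coef_width_h = coef_width_h, coef_stride_h = coef_stride_h,
      diff_absolute = diff_absolute,
      thresholds = thresholds,
      version = "1"
    ),
    class = "icp_grammar"
  )
}

render_feature_name <- function(signal, stat, aggregation) {
  if_else(stat == "avg", paste(signal, aggregation, sep = "_"),
          paste(signal, stat, aggregation, sep = "_"))
}

#' Enumerate the candidate feature set
#'
#' Deterministic order: signal, then statistic, then aggregation, with `agec`
#' last. The plain-mean features render without the stat token (`icp_end`,
#' `icp_coef`, ...).
#'
#' @param grammar A [feature_grammar()].
#' @return Tibble with columns `name`, `signal`, `stat`, `aggregation`.
#' @export
enumerate_candidate_features <- function(grammar = feature_grammar()) {
  rows <- purrr::map(grammar$signals, function(sig) {
    stats_sig <- c(grammar$stats, grammar$threshold_stats[[sig]])
    tidyr::expand_grid(signal = sig, stat = stats_sig,
                       aggregation = grammar$aggregations)
  }) |> purrr::list_rbind()
  rows |>
    mutate(name = render_feature_name(.data$signal, .data$stat,
                                      .data$aggregation)) |>
    bind_rows(tibble(signal = "age", stat = NA_character_,
                     aggregation = NA_character_, name = "agec")) |>
    select("name", "signal", "stat", "aggregation")
}

#' Stable hash of a feature grammar
#'
#' Used to refuse prediction when a model artifact and a feature table were
#' produced under different grammars.
#'
#' @param grammar A [feature_grammar()].
#' @return A 32-character hexadecimal string.
#' @export
grammar_hash <- function(grammar) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(unclass(grammar), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Prediction schedule
#'
#' Scheduled prediction times in hours: every 8 h from 24 h to 120 h.
#'
#' @param from,to,by Schedule bounds and step in hours.
#' @return Numeric vector of prediction times.
#' @export
prediction_schedule <- function(from = 24, to = 120, by = 8) {
  seq(from, to, by = by)
}

# Per-patient, per-signal feature block. series: tibble(time_min, value)
# sorted. Returns named list: begin stats, and per-t end stats + coef slopes.
featurize_signal <- function(series, signal, t_hs, grammar) {
  stats_sig <- c(grammar$stats, grammar$threshold_stats[[signal]])
  tv <- series$time_min
  v <- series$value
  slice_vals <- function(a, b) v[tv >= a & tv < b]
  wstats <- function(vals) {
    s <- compute_window_stats(vals, stats_sig)
    if (grammar$diff_absolute && "diff" %in% stats_sig && length(vals) >= 2) {
      s["diff"] <- mean(abs(diff(vals)))
    }
    s
  }

  begin <- wstats(slice_vals(0, grammar$begin_h * 60))

  # rolling 4-h windows ending at whole hours coef_width_h .. max(t)
  ends <- seq(grammar$coef_width_h, max(t_hs), by = grammar$coef_stride_h)
  roll <- matrix(NA_real_, nrow = length(ends), ncol = length(stats_sig),
                 dimnames = list(NULL, stats_sig))
  for (i in seq_along(ends)) {
    roll[i, ] <- wstats(slice_vals((ends[i] - grammar$coef_width_h) * 60,
                                   ends[i] * 60))
  }

  per_t <- purrr::map(t_hs, function(t_h) {
    end <- wstats(slice_vals((t_h - grammar$end_h) * 60, t_h * 60))
    keep <- ends <= t_h
    coef <- vapply(stats_sig, function(st) ols_slope(ends[keep], roll[keep, st]),
                   numeric(1))
    list(end = end, coef = coef)
  })
  names(per_t) <- as.character(t_hs)
  list(begin = begin, per_t = per_t)
}

#' Evaluate the candidate features for a cohort
#'
#' Computes every feature of the grammar for each patient at each scheduled
#' prediction time the patient is monitored through (a scheduled `t` is
#' skipped when monitoring ended before `t`; "through" tolerates the last
#' sample falling up to 5 min — the coarsest storage resolution — short of
#' `t`, since the horizon and all windows are half-open). A feature is `NA` exactly when
#' its window holds no samples (or a single sample, for `diff`/`var`, or
#' fewer than two non-missing rolling windows, for `coef`); such patients are
#' later excluded from that time-point's estimate rather than imputed.
#'
#' @param cohort An `icp_cohort` from [prepare_cohort()] or
#'   [generate_cohort()].
#' @param times Prediction times in hours; default [prediction_schedule()].
#' @param grammar A [feature_grammar()].
#' @param quiet Suppress progress messages.
#' @return A tibble of class `icp_features`: one row per (patient,
#'   prediction time), columns `patient_id`, `t_h`, the 55 candidate
#'   features, and `outcome`. Attribute `grammar_hash` records the grammar.
#' @export
featurize <- function(cohort, times = prediction_schedule(),
                      grammar = feature_grammar(), quiet = FALSE) {
  stopifnot(inherits(cohort, "icp_cohort"))
  if (any(times < 24) || any((times - 24) %% 8 != 0)) {
    stop_icpdyn("prediction times must be 24 + multiples of 8 hours")
  }
  feats <- enumerate_candidate_features(grammar)
  sig_feats <- filter(feats, .data$name != "agec")
  by_sig <- split(sig_feats, sig_feats$signal)

  vit <- cohort$vitals |> arrange(.data$patient_id, .data$signal, .data$time_min)
  vit_split <- split(select(vit, "time_min", "value", "signal"),
                     vit$patient_id)

  rows <- list()
  for (p in seq_len(nrow(cohort$patients))) {
    pid <- cohort$patients$patient_id[p]
    end_min <- cohort$patients$monitoring_end_min[p]
    # a scheduled t counts as monitored through when the last sample falls
    # within 5 min (the coarsest storage resolution) of t: the horizon and
    # all windows are half-open, so a fully monitored patient's last sample
    # sits just short of t*60
    t_hs <- times[times * 60 - 5 <= end_min]
    if (length(t_hs) == 0) next
    pv <- vit_split[[pid]]
    blocks <- purrr::map(
      setNames(grammar$signals, grammar$signals),
      function(sig) {
        featurize_signal(pv[pv$signal == sig, , drop = FALSE], sig, t_hs,
                         grammar)
      })
    for (t_h in t_hs) {
      vals <- purrr::pmap_dbl(
        list(sig_feats$signal, sig_feats$stat, sig_feats$aggregation),
        function(sig, st, agg) {
          b <- blocks[[sig]]
          switch(agg,
                 begin = b$begin[[st]],
                 end = b$per_t[[as.character(t_h)]]$end[[st]],
                 coef = b$per_t[[as.character(t_h)]]$coef[[st]])
        })
      rows[[length(rows) + 1L]] <- c(
        list(patient_id = pid, t_h = t_h),
        setNames(as.list(vals), sig_feats$name),
        list(agec = as.numeric(age_decile(cohort$patients$age_years[p])),
             outcome = cohort$patients$outcome[p]))
    }
  }
  out <- bind_rows(rows)
  inform_counts("featurize: ", nrow(out), " (patient, time) rows, ",
                nrow(feats), " candidate features", quiet = quiet)
  structure(out, grammar_hash = grammar_hash(grammar),
            class = c("icp_features", class(out)))
}

#' Write / read a feature table
#'
#' Wide CSV: one row per (patient, prediction time); missing features are
#' empty cells. The grammar hash travels in a sidecar comment-free JSON
#' header file written next to the CSV (`<path>.meta.json`).
#'
#' @param features An `icp_features` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, na = "")
  jsonlite::write_json(
    list(grammar_hash = attr(features, "grammar_hash"),
         n_rows = nrow(features)),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- mutate(df, patient_id = as.character(.data$patient_id))
  meta_path <- paste0(path, ".meta.json")
  h <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path)$grammar_hash
  } else {
    NULL
  }
  structure(df, grammar_hash = h, class = c("icp_features", class(df)))
}
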
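# Synthetic TBI neuromonitoring cohorts.
#
# The generator produces minute-gridded ICP/MAP series with the statistical
# structure the dynamic model assumes: a latent severity score drives both
# the 30-day-mortality outcome (through a calibrated logistic link) and the
# ICP process (a level shift for sicker patients plus, in non-survivors, a
# slow upward drift — the sole time-growing signal, which is what makes
# "prediction improves with monitoring time" a designed-in, testable
# property). MAP is outcome-independent by default, so CPP inherits ICP's
# signal. Block missingness and out-of-range artifact spikes are injected so
# the preprocessing filters are exercised. Presets mimic the published
# demographics of the three study cohorts.

cohort_presets <- function() {
  list(
    training = list(n_patients = 686L, mortality_target = 0.17,
                    age_median = 46, age_iqr = c(28, 59),
                    duration_mean = 90.7, duration_sd = 31.4),
    stockholm = list(n_patients = 464L, mortality_target = 0.13,
                     age_median = 51, age_iqr = c(33, 62),
                     duration_mean = 90.7, duration_sd = 31.4),
    eicu = list(n_patients = 174L, mortality_target = 0.30,
                age_median = 38, age_iqr = c(24, 57),
                duration_mean = 90.7, duration_sd = 31.4)
  )
}

# Moments of a censored normal: X = clip(N(mu, sigma), lo, hi) with point
# masses at the bounds.
censored_normal_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  p_lo <- pnorm(a); p_hi <- 1 - pnorm(b); p_mid <- pnorm(b) - pnorm(a)
  m1_mid <- mu * p_mid - sigma * (dnorm(b) - dnorm(a))
  int_z2 <- p_mid + a * dnorm(a) - b * dnorm(b)
  m2_mid <- mu^2 * p_mid + 2 * mu * sigma * (dnorm(a) - dnorm(b)) +
    sigma^2 * int_z2
  m1 <- lo * p_lo + hi * p_hi + m1_mid
  m2 <- lo^2 * p_lo + hi^2 * p_hi + m2_mid
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Solve for the parent (mu, sigma) whose censored-on-[lo,hi] distribution
# has the requested mean and SD. Deterministic Nelder-Mead refinement.
calibrate_censored_normal <- function(mean_target, sd_target, lo, hi) {
  obj <- function(par) {
    m <- censored_normal_moments(par[1], exp(par[2]), lo, hi)
    (m["mean"] - mean_target)^2 + (m["sd"] - sd_target)^2
  }
  fit <- optim(c(mean_target, log(sd_target)), obj,
               control = list(maxit = 2000, reltol = 1e-14))
  m <- censored_normal_moments(fit$par[1], exp(fit$par[2]), lo, hi)
  if (abs(m["mean"] - mean_target) > 0.05 * mean_target ||
      abs(m["sd"] - sd_target) > 0.1 * sd_target) {
    stop_icpdyn(sprintf(
      "cannot realise a censored-normal duration with mean %.1f / sd %.1f on [%g, %g]",
      mean_target, sd_target, lo, hi))
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]), achieved = m)
}

# Intercept a with E[plogis(a + slope * Z)] = target, Z ~ N(0,1).
calibrate_link_intercept <- function(target, slope) {
  if (!is.numeric(target) || target <= 0 || target >= 1) {
    stop_icpdyn("mortality_target must lie strictly inside (0, 1)")
  }
  prev <- function(a) {
    stats::integrate(function(z) plogis(a + slope * z) * dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value - target
  }
  uniroot(prev, c(-30, 30), tol = 1e-10)$root
}

#' Synthetic-cohort generator configuration
#'
#' Builds the full parameter set for [generate_cohort()], starting from a
#' named preset that matches one published cohort's demographics (mortality,
#' median age and IQR, mean/SD of monitoring duration) and filling in the
#' physiological and nuisance parameters. Any field can be overridden via
#' `...`. Derived calibrations (the logistic-link intercept hitting the
#' mortality target; the censored-normal duration parent hitting the
#' printed duration mean/SD on the eligible range 24-120 h) are solved
#' numerically at construction.
#'
#' @param preset `"training"`, `"stockholm"` or `"eicu"`.
#' @param n_patients Number of patients; default: the preset's cohort size.
#' @param seed Integer seed; all randomness flows through it.
#' @param ... Overrides for any configuration field, e.g.
#'   `severity_drift = 0`, `artifact_rate = 2`.
#' @return An object of class `icp_sim_config`. Key fields (units):
#'   `mortality_target` (proportion), `age_median`/`age_iqr` (years),
#'   `duration_mean`/`duration_sd` (hours, censored to 24-120),
#'   `icp_baseline_mean`/`icp_baseline_sd` (mmHg, between-patient),
#'   `severity_shift` (mmHg per severity SD), `severity_drift`
#'   (mmHg/h per severity SD, non-survivors only), `map_mean`/`map_sd`
#'   (mmHg), `ou_mean_reversion` (per hour), `icp_noise_sd`/`map_noise_sd`
#'   (mmHg, stationary within-patient SD), `missing_block_rate` (blocks per
#'   24 h per signal), `missing_block_length` (minutes), `artifact_rate`
#'   (per 1000 samples), `sample_interval` (minutes),
#'   `severity_link_slope` (log-odds per severity SD),
#'   `death_truncation` (logical), `death_time_meanlog`/`sdlog` (hours).
#' @export
generator_config <- function(preset = c("training", "stockholm", "eicu"),
                             n_patients = NULL, seed = 1L, ...) {
  preset <- match.arg(preset)
  p <- cohort_presets()[[preset]]
  cfg <- list(
    preset = preset,
    n_patients = as.integer(n_patients %||% p$n_patients),
    mortality_target = p$mortality_target,
    age_median = p$age_median, age_iqr = p$age_iqr,
    age_range = c(16, 95),
    duration_mean = p$duration_mean, duration_sd = p$duration_sd,
    duration_range = c(24, 120),
    icp_baseline_mean = 12, icp_baseline_sd = 3,
    severity_shift = 2, severity_drift = 0.08,
    map_mean = 85, map_sd = 7,
    ou_mean_reversion = 0.5,
    icp_noise_sd = 4, map_noise_sd = 8,
    missing_block_rate = 1, missing_block_length = 60,
    artifact_rate = 0.5,
    sample_interval = 2,
    severity_link_slope = 1.5,
    death_truncation = TRUE,
    death_time_meanlog = log(140), death_time_sdlog = 0.8,
    map_outcome_coupling = 0,
    seed = as.integer(seed)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop_icpdyn(paste0("unknown generator field(s): ",
                       paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$sample_interval >= 1, cfg$artifact_rate >= 0,
            cfg$missing_block_rate >= 0)
  cfg$link_intercept <- calibrate_link_intercept(cfg$mortality_target,
                                                 cfg$severity_link_slope)
  dur <- calibrate_censored_normal(cfg$duration_mean, cfg$duration_sd,
                                   cfg$duration_range[1],
                                   cfg$duration_range[2])
  cfg$duration_mu <- dur$mu
  cfg$duration_sigma <- dur$sigma
  structure(cfg, class = "icp_sim_config")
}

# two-piece normal hitting the preset median and IQR, clipped to age_range
draw_age <- function(cfg) {
  s_lo <- (cfg$age_median - cfg$age_iqr[1]) / qnorm(0.75)
  s_hi <- (cfg$age_iqr[2] - cfg$age_median) / qnorm(0.75)
  lower <- runif(1) < 0.5
  a <- cfg$age_median + (if (lower) -s_lo else s_hi) * abs(rnorm(1))
  min(max(a, cfg$age_range[1]), cfg$age_range[2])
}

# AR(1) exact discretisation of an OU process around a (possibly
# time-varying) mean; sd is the stationary SD.
ou_series <- function(mean_path, theta, sd, dt_h) {
  n <- length(mean_path)
  rho <- exp(-theta * dt_h)
  innov_sd <- sd * sqrt(1 - rho^2)
  e <- rnorm(n - 1, 0, innov_sd)
  x0 <- rnorm(1, 0, sd)
  dev <- stats::filter(c(x0, e), rho, method = "recursive")
  mean_path + as.numeric(dev)
}

inject_artifacts <- function(values, signal, rate_per_1000) {
  n <- length(values)
  hit <- which(runif(n) < rate_per_1000 / 1000)
  if (length(hit) == 0) return(values)
  high <- runif(length(hit)) < 0.5
  values[hit] <- if (signal == "icp") {
    if_else(high, runif(length(hit), 101, 160), runif(length(hit), -30, -1))
  } else {
    if_else(high, runif(length(hit), 151, 260), runif(length(hit), 1, 19))
  }
  values
}

drop_missing_blocks <- function(time_min, cfg) {
  span_h <- (max(time_min) + 1) / 60
  n_blocks <- rpois(1, cfg$missing_block_rate * span_h / 24)
  keep <- rep(TRUE, length(time_min))
  if (n_blocks > 0) {
    starts <- runif(n_blocks, 0, max(time_min))
    for (s in starts) {
      keep[time_min >= s & time_min < s + cfg$missing_block_length] <- FALSE
    }
  }
  keep
}

#' Generate one synthetic neuromonitoring patient
#'
#' Draws from the generator's probabilistic model: age (two-piece normal
#' matched to the preset median/IQR), latent severity (standard normal),
#' outcome (logistic link on severity, intercept calibrated to the
#' mortality target), monitoring duration (censored normal on 24-120 h),
#' then minute-gridded ICP and MAP as mean-reverting (OU) processes — ICP
#' centred on baseline + severity shift with an additional per-hour drift
#' for non-survivors — with missing blocks and out-of-range artifact spikes
#' injected. Non-survivors' monitoring is additionally truncated at a
#' simulated death time (floored at the 24-h eligibility bound).
#'
#' Uses the current RNG state unless `seed` is given; [generate_cohort()]
#' seeds once and calls this sequentially, which makes whole cohorts
#' reproducible bit-for-bit.
#'
#' @param config An [generator_config()].
#' @param patient_id Identifier for the emitted rows.
#' @param seed Optional integer seed for a standalone reproducible draw.
#' @return List with `vitals` (tibble `patient_id, time_min, signal, value` —
#'   raw, artifact-bearing, pre-filter), `meta` (one-row tibble with
#'   `age_years`, `outcome`) and `truth` (one-row tibble with the latent
#'   state: `severity`, `p_death`, `duration_raw_h` pre-death-truncation,
#'   `death_h`, `monitoring_end_min`).
#' @export
generate_patient <- function(config, patient_id = "p1", seed = NULL) {
  stopifnot(inherits(config, "icp_sim_config"))
  if (!is.null(seed)) set.seed(seed)

  age <- draw_age(config)
  severity <- rnorm(1)
  p_death <- plogis(config$link_intercept +
                      config$severity_link_slope * severity)
  outcome <- rbinom(1, 1, p_death)

  duration_raw_h <- min(max(rnorm(1, config$duration_mu,
                                  config$duration_sigma),
                            config$duration_range[1]),
                        config$duration_range[2])
  death_h <- rlnorm(1, config$death_time_meanlog, config$death_time_sdlog)
  end_h <- duration_raw_h
  if (config$death_truncation && outcome == 1L) {
    end_h <- min(end_h, max(death_h, config$duration_range[1]))
  }
  end_min <- round(end_h * 60)

  tgrid <- seq(0L, as.integer(end_min), by = as.integer(config$sample_interval))
  t_h <- tgrid / 60
  dt_h <- config$sample_interval / 60

  icp_level <- config$icp_baseline_mean +
    config$icp_baseline_sd * rnorm(1) + config$severity_shift * severity
  drift <- if (outcome == 1L) config$severity_drift * severity else 0
  icp <- ou_series(icp_level + drift * t_h, config$ou_mean_reversion,
                   config$icp_noise_sd, dt_h)

  map_level <- config$map_mean + config$map_sd * rnorm(1) +
    config$map_outcome_coupling * severity * (outcome == 1L)
  map <- ou_series(rep(map_level, length(tgrid)), config$ou_mean_reversion,
                   config$map_noise_sd, dt_h)

  icp <- inject_artifacts(icp, "icp", config$artifact_rate)
  map <- inject_artifacts(map, "map", config$artifact_rate)
  keep_icp <- drop_missing_blocks(tgrid, config)
  keep_map <- drop_missing_blocks(tgrid, config)

  vitals <- bind_rows(
    tibble(patient_id = patient_id, time_min = tgrid[keep_icp],
           signal = "icp", value = icp[keep_icp]),
    tibble(patient_id = patient_id, time_min = tgrid[keep_map],
           signal = "map", value = map[keep_map])
  )
  list(
    vitals = vitals,
    meta = tibble(patient_id = patient_id, age_years = age,
                  outcome = as.integer(outcome)),
    truth = tibble(patient_id = patient_id, severity = severity,
                   p_death = p_death, duration_raw_h = duration_raw_h,
                   death_h = if (outcome == 1L) death_h else NA_real_,
                   monitoring_end_min = as.integer(end_min))
  )
}

#' Generate a synthetic cohort
#'
#' Seeds the RNG once from `config$seed` and draws `n_patients` patients
#' sequentially, so regeneration under the same configuration is
#' byte-identical.
#'
#' @param config An [generator_config()].
#' @param quiet Suppress the summary message.
#' @return An object of class `icp_sim`: list with `vitals` (raw long
#'   tibble, artifacts included), `metadata` (`patient_id, age_years,
#'   outcome`), `ground_truth` (latent severities, death probabilities, raw
#'   durations, death times) and `config`.
#' @export
generate_cohort <- function(config = generator_config(), quiet = FALSE) {
  stopifnot(inherits(config, "icp_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("p%05d", seq_len(n))
  drawn <- purrr::map(ids, function(id) generate_patient(config, id))
  schema <- list(
    vitals = tibble(patient_id = character(), time_min = integer(),
                    signal = character(), value = double()),
    meta = tibble(patient_id = character(), age_years = double(),
                  outcome = integer()),
    truth = tibble(patient_id = character(), severity = double(),
                   p_death = double(), duration_raw_h = double(),
                   death_h = double(), monitoring_end_min = integer()))
  take <- function(field) {
    if (n == 0) return(schema[[field]])
    purrr::list_rbind(purrr::map(drawn, field))
  }
  out <- structure(
    list(vitals = take("vitals"), metadata = take("meta"),
         ground_truth = take("truth"), config = config),
    class = "icp_sim")
  inform_counts("generate_cohort: ", n, " patients (preset '", config$preset,
                "'), observed mortality ",
                sprintf("%.1f%%", 100 * mean(out$metadata$outcome)),
                quiet = quiet)
  out
}

#' @export
print.icp_sim <- function(x, ...) {
  cat(sprintf(
    "<icp_sim> preset '%s': %d patients, %d raw samples, mortality %.1f%%\n",
    x$config$preset, nrow(x$metadata), nrow(x$vitals),
    100 * mean(x$metadata$outcome)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `vitals.csv` and `metadata.csv` in the dialect the preprocessing
#' readers consume, plus `ground_truth.csv` (latent state sidecar for
#' parameter-recovery tests) and `config.json` (resolved configuration
#' snapshot).
#'
#' @param sim An `icp_sim` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "icp_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(mutate(sim$vitals, signal = toupper(.data$signal)),
                   file.path(dir, "vitals.csv"))
  readr::write_csv(sim$metadata, file.path(dir, "metadata.csv"))
  readr::write_csv(sim$ground_truth, file.path(dir, "ground_truth.csv"))
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
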
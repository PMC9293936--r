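# Shared fixtures, built in code and memoised so expensive objects are
# generated once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

make_series <- function(time_min, value) {
  tibble::tibble(time_min = as.integer(time_min), value = as.numeric(value))
}

# hand-built single-patient cohort wrapper (already preprocessed vitals)
make_cohort <- function(vitals, age_years = 40, outcome = 0L,
                        patient_id = "p1") {
  vitals$patient_id <- patient_id
  structure(
    list(vitals = vitals,
         patients = tibble::tibble(patient_id = patient_id,
                                   age_years = age_years,
                                   outcome = as.integer(outcome),
                                   monitoring_end_min = max(vitals$time_min))),
    class = "icp_cohort")
}

# dense, gap-free patient: every signal sampled each minute over hours_total
dense_vitals <- function(hours_total = 48, icp = 15, map = 85) {
  t <- 0:(hours_total * 60 - 1)
  icp_v <- if (length(icp) == 1) rep(icp, length(t)) else icp
  map_v <- if (length(map) == 1) rep(map, length(t)) else map
  dplyr::bind_rows(
    tibble::tibble(time_min = t, signal = "icp", value = icp_v),
    tibble::tibble(time_min = t, signal = "map", value = map_v),
    tibble::tibble(time_min = t, signal = "cpp", value = map_v - icp_v))
}

small_sim <- function() fixture("small_sim", function() {
  generate_cohort(generator_config("training", n_patients = 60, seed = 11),
                  quiet = TRUE)
})

small_cohort <- function() fixture("small_cohort", function() {
  sim <- small_sim()
  suppressMessages(prepare_cohort(sim$vitals, sim$metadata, quiet = TRUE))
})

small_features <- function() fixture("small_features", function() {
  featurize(small_cohort(), quiet = TRUE)
})

# O(n^2) pairwise concordance oracle for the AUC
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exhaustive-threshold PR sweep oracle for the AUPRC
pr_auc_oracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    prec[i] <- sum(labels == 1 & pred) / sum(pred)
    rec[i] <- sum(labels == 1 & pred) / sum(labels == 1)
  }
  sum(diff(c(0, rec)) * prec)
}

# closed-form OLS slope
slope_oracle <- function(x, y) {
  ok <- !is.na(y); x <- x[ok]; y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
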
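# Pooled dynamic logistic model: row assembly, the ridge-IRLS fit,
# prediction, classification, folds, RFE and internal CV.

sim_rows <- function(n, p = 3, beta = c(2, rep(0, 2)), intercept = -1,
                     seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rbinom(n, 1, plogis(intercept + drop(x %*% beta)))
  list(x = x, y = y)
}

test_that("assemble_training_rows pools (patient, time) rows grouped by patient", {
  fv <- tibble::tibble(
    patient_id = rep(c("a", "b"), each = 2), t_h = rep(c(24, 32), 2),
    f1 = rnorm(4), f2 = c(1, NA, 0, 2), outcome = rep(c(1L, 0L), each = 2))
  rows <- assemble_training_rows(fv, quiet = TRUE)
  expect_equal(nrow(rows$x), 3L)        # NA row dropped
  expect_equal(sort(unique(rows$groups)), c("a", "b"))
  expect_true(all(rows$y[rows$groups == "a"] == 1))

  one_class <- dplyr::mutate(fv, outcome = 0L)
  expect_error(assemble_training_rows(one_class, quiet = TRUE), "single outcome")

  drifting <- fv; drifting$outcome <- c(1L, 0L, 0L, 0L)
  expect_error(assemble_training_rows(drifting, quiet = TRUE), "varies")
})

test_that("fit_logistic approaches the null model on uninformative features", {
  d <- sim_rows(20000, p = 2, beta = c(0, 0), intercept = qlogis(0.3),
                seed = 2)
  fit <- fit_logistic(d$x, d$y)
  td <- tidy(fit)
  expect_lt(max(abs(td$std_estimate[-1])), 0.06)
  expect_equal(td$estimate[1], qlogis(mean(d$y)), tolerance = 0.05)
})

test_that("fit_logistic recovers a planted coefficient at n = 10,000", {
  d <- sim_rows(10000, p = 1, beta = 2, intercept = 0, seed = 3)
  fit <- fit_logistic(d$x, d$y)
  est <- tidy(fit)$estimate[2]   # natural scale; x ~ N(0,1)
  expect_lt(abs(est - 2), 0.15)
})

test_that("fit_logistic is deterministic and agrees with glm at tiny ridge", {
  d <- sim_rows(800, p = 4, beta = c(1, -0.5, 0, 0.3), seed = 4)
  f1 <- fit_logistic(d$x, d$y, lambda = 1e-10)
  f2 <- fit_logistic(d$x, d$y, lambda = 1e-10)
  expect_identical(f1$weights, f2$weights)  # bitwise

  ref <- stats::glm(d$y ~ d$x, family = stats::binomial())
  expect_equal(tidy(f1)$estimate, unname(stats::coef(ref)), tolerance = 1e-5)
})

test_that("duplicating a patient's rows equals case weighting (glm oracle)", {
  d <- sim_rows(300, p = 2, beta = c(1, -1), seed = 5)
  dup_idx <- c(seq_len(300), rep(1:20, 2))   # first 20 rows tripled
  fit_dup <- fit_logistic(d$x[dup_idx, ], d$y[dup_idx], lambda = 1e-10)
  w <- c(rep(3, 20), rep(1, 280))
  ref <- suppressWarnings(
    stats::glm(d$y ~ d$x, family = stats::binomial(), weights = w))
  expect_equal(tidy(fit_dup)$estimate, unname(stats::coef(ref)),
               tolerance = 1e-4)
})

test_that("zero-variance features are dropped with a warning", {
  d <- sim_rows(200, p = 2, beta = c(1, 0), seed = 6)
  x <- cbind(d$x, flat = 5)
  expect_warning(fit <- fit_logistic(x, d$y), "zero-variance")
  expect_false("flat" %in% fit$features)
})

test_that("predict_risk obeys the null-model and monotonicity contracts", {
  fv <- small_features()
  model <- structure(
    list(fit = structure(
      list(intercept = 0, weights = c(icp_end = 0), center = c(icp_end = 0),
           scale = c(icp_end = 1), features = "icp_end", lambda = 0,
           nobs = 1L, prevalence = 0.5, converged = TRUE, deviance = 0),
      class = "icp_fit"),
      selected = "icp_end", grammar_hash = attr(fv, "grammar_hash")),
    class = "icp_model")
  pr <- predict_risk(model, fv)
  expect_true(all(pr$probability[!is.na(pr$probability)] == 0.5))

  model$fit$intercept <- qlogis(0.17)
  pr <- predict_risk(model, fv)
  expect_equal(unique(stats::na.omit(pr$probability)), 0.17)

  # positive weight on icp_end: raising icp_end strictly raises the risk
  model$fit$weights <- c(icp_end = 0.8)
  fv2 <- dplyr::mutate(fv, icp_end = icp_end + 5)
  p1 <- predict_risk(model, fv)$probability
  p2 <- predict_risk(model, fv2)$probability
  ok <- !is.na(p1)
  expect_true(all(p2[ok] > p1[ok]))

  # a missing selected feature yields an absent prediction
  fv3 <- fv; fv3$icp_end[1] <- NA
  expect_true(is.na(predict_risk(model, fv3)$probability[1]))

  model$fit$features <- model$selected <- "no_such_feature"
  expect_error(predict_risk(model, fv), "absent")
})

test_that("classify uses a strict > threshold", {
  expect_equal(as.character(classify(0.51, 0.5)), "death")
  expect_equal(as.character(classify(0.50, 0.5)), "survival")
  expect_equal(as.character(classify(0.30, 0.25)), "death")
  expect_equal(as.character(classify(0.30, 0.75)), "survival")
  expect_true(is.na(classify(NA_real_, 0.5)))
  expect_error(classify(0.5, 0), "0, 1")
  expect_error(classify(0.5, 1), "0, 1")
  expect_error(classify(1.2, 0.5), "0, 1")
})

test_that("stratified folds partition patients and balance prevalence", {
  set.seed(20)
  ids <- sprintf("p%03d", 1:97)
  y <- rbinom(97, 1, 0.2)
  fold <- stratified_group_folds(ids, y, 5, seed = 9)
  expect_equal(length(fold), 97L)
  expect_true(all(fold %in% 1:5))
  expect_equal(sum(table(fold)), 97L)   # every patient exactly once
  per_fold_deaths <- tapply(y, fold, sum)
  expect_lte(diff(range(per_fold_deaths)), 1)
  per_fold_alive <- tapply(1 - y, fold, sum)
  expect_lte(diff(range(per_fold_alive)), 1)
})

test_that("standardization round-trips: stored model reproduces in-sample fit", {
  d <- sim_rows(400, p = 3, beta = c(1, -0.7, 0.2), seed = 7)
  fit <- fit_logistic(d$x, d$y)
  td <- tidy(fit)
  eta <- td$estimate[1] + drop(d$x %*% td$estimate[-1])
  fv <- tibble::as_tibble(d$x)
  fv$patient_id <- as.character(seq_len(400)); fv$t_h <- 24
  pr <- predict_risk(fit, fv, check_hash = FALSE)
  expect_equal(pr$probability, plogis(eta), tolerance = 1e-8)
})

test_that("CV AUC is near 0.5 when labels are permuted against features", {
  d <- sim_rows(1000, p = 10, beta = c(1.5, -1, rep(0, 8)), seed = 30)
  set.seed(31)
  y_perm <- sample(d$y)   # break every feature-label association
  ids <- as.character(seq_len(1000))
  fold <- stratified_group_folds(ids, y_perm, 5, seed = 8)
  aucs <- vapply(1:5, function(f) {
    tr <- fold != f
    fit <- fit_logistic(d$x[tr, ], y_perm[tr])
    fv <- tibble::as_tibble(d$x[!tr, ])
    fv$patient_id <- ids[!tr]; fv$t_h <- 24
    pr <- predict_risk(fit, fv, check_hash = FALSE)
    roc_auc(pr$probability, y_perm[!tr])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("rfe_select degenerates to the full model when the grid is all features", {
  fv <- small_features()
  rows <- assemble_training_rows(fv, quiet = TRUE)
  sel <- suppressWarnings(
    rfe_select(rows, training_config(seed = 2, rfe_grid = ncol(rows$x))))
  expect_equal(sel$n_selected, ncol(rows$x))
  expect_setequal(sel$selected, colnames(rows$x))
})

test_that("rfe_select keeps planted informative features against noise", {
  set.seed(40)
  n <- 600; p_noise <- 10
  info <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(NULL, paste0("inf", 1:3)))
  noise <- matrix(rnorm(n * p_noise), n, p_noise,
                  dimnames = list(NULL, paste0("noise", 1:p_noise)))
  y <- rbinom(n, 1, plogis(-1 + drop(info %*% c(1.2, -1, 0.9))))
  rows <- list(x = cbind(info, noise), y = y,
               groups = as.character(seq_len(n)))
  sel <- rfe_select(rows, training_config(seed = 3))
  expect_true(all(paste0("inf", 1:3) %in% sel$selected))
  expect_equal(nrow(sel$cv_report), 13L)
  expect_true(all(diff(sel$cv_report$n_features) > 0))
})

test_that("different fold seeds may select different subsets, both recorded", {
  fv <- small_features()
  rows <- assemble_training_rows(fv, quiet = TRUE)
  grid <- c(2, 5, 10, 20, 40, 55)
  s1 <- suppressWarnings(rfe_select(rows, training_config(seed = 1,
                                                          rfe_grid = grid)))
  s2 <- suppressWarnings(rfe_select(rows, training_config(seed = 99,
                                                          rfe_grid = grid)))
  expect_equal(s1$seed, 1L)
  expect_equal(s2$seed, 99L)
  expect_s3_class(s1$cv_report, "tbl_df")
  # identical seeds must reproduce the subset exactly
  s1b <- suppressWarnings(rfe_select(rows, training_config(seed = 1,
                                                           rfe_grid = grid)))
  expect_identical(s1$selected, s1b$selected)
})

test_that("model artifacts round-trip through JSON with identical predictions", {
  fv <- small_features()
  model <- suppressWarnings(
    fit_dynamic_model(fv, training_config(seed = 5,
                                          rfe_grid = c(2, 5, 10, 25, 55)),
                      quiet = TRUE))
  dir <- withr::local_tempdir()
  write_model(model, file.path(dir, "m.json"))
  back <- read_model(file.path(dir, "m.json"))
  expect_identical(back$selected, model$selected)
  p1 <- predict_risk(model, fv)
  p2 <- predict_risk(back, fv)
  expect_equal(p2$probability, p1$probability, tolerance = 1e-12)
})

test_that("run_internal_cv partitions patients and returns valid curves", {
  fv <- small_features()
  cv <- suppressWarnings(
    run_internal_cv(fv, training_config(seed = 4,
                                        rfe_grid = c(2, 5, 10, 25, 55)),
                    quiet = TRUE))
  preds <- cv$predictions
  # each patient is held out exactly once
  pf <- dplyr::distinct(preds, patient_id, fold)
  expect_equal(nrow(pf), dplyr::n_distinct(preds$patient_id))
  expect_true(all(preds$probability >= 0 & preds$probability <= 1,
                  na.rm = TRUE))
  expect_true(all(c("auc", "auprc", "fp_rate", "fn_rate", "n_evaluated")
                  %in% names(cv$curves)))
  expect_equal(length(cv$selected), 5L)  # one feature list per fold
})
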
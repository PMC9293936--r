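# The time-window dynamic logistic model.
#
# One logistic regression with *constant* coefficients is fit on rows pooled
# across prediction times (one row per patient x scheduled time, the
# patient's 30-day-mortality label repeated); the dynamics come entirely from
# the time-varying features. Cross-validation always splits by patient —
# never by row — so a patient's own later time-points cannot leak into the
# training folds.

#' Training configuration
#'
#' @param n_folds Folds for stratified patient-level cross-validation
#'   (default 5).
#' @param rfe_grid Candidate feature-count set scored during recursive
#'   feature elimination; `NULL` (default) scores every count from 1 to the
#'   number of candidates.
#' @param seed Integer seed driving every fold shuffle.
#' @param lambda Ridge strength of the weak L2 penalty used for numerical
#'   stability (per-observation scale; default `1e-6`, i.e. negligible —
#'   effectively plain maximum likelihood).
#' @param pooling Row-assembly flag; `"pooled"` (the only implemented
#'   scheme) pools rows across prediction times under constant coefficients.
#' @return An object of class `icp_training_config`.
#' @export
training_config <- function(n_folds = 5, rfe_grid = NULL, seed = 1,
                            lambda = 1e-6, pooling = "pooled") {
  stopifnot(n_folds >= 2, lambda >= 0)
  structure(list(n_folds = as.integer(n_folds), rfe_grid = rfe_grid,
                 seed = as.integer(seed), lambda = lambda, pooling = pooling),
            class = "icp_training_config")
}

#' Assemble pooled training rows from a feature table
#'
#' One design row per (patient, prediction time); the patient's outcome label
#' is repeated across their rows and the patient id is retained as the
#' grouping key for patient-level fold splitting. Rows with any missing value
#' among the requested features are dropped (and counted): patients with a
#' completely missing window are excluded from that time-point, never
#' imputed.
#'
#' @param features An `icp_features` tibble from [featurize()].
#' @param feature_names Features to keep; default: all candidate columns.
#' @param quiet Suppress the dropped-row message.
#' @return List with `x` (numeric matrix), `y` (0/1 vector), `groups`
#'   (patient ids), `t_h`, and `data` (the retained rows).
#' @export
assemble_training_rows <- function(features, feature_names = NULL,
                                   quiet = FALSE) {
  assert_columns(features, c("patient_id", "t_h", "outcome"), "features")
  feature_names <- feature_names %||%
    setdiff(names(features), c("patient_id", "t_h", "outcome"))
  assert_columns(features, feature_names, "features")
  lab <- features |>
    group_by(.data$patient_id) |>
    summarise(k = n_distinct(.data$outcome), .groups = "drop")
  if (any(lab$k != 1)) {
    stop_icpdyn("outcome label varies within a patient", "icpdyn_data_error")
  }
  if (n_distinct(features$outcome) < 2) {
    stop_icpdyn("cohort has a single outcome class; model is unfittable",
                "icpdyn_data_error")
  }
  x <- as.matrix(features[, feature_names, drop = FALSE])
  keep <- stats::complete.cases(x)
  inform_counts("assemble_training_rows: ", sum(!keep), " of ", nrow(x),
                " rows dropped for missing features", quiet = quiet)
  kept <- features[keep, , drop = FALSE]
  list(x = x[keep, , drop = FALSE], y = as.numeric(kept$outcome),
       groups = kept$patient_id, t_h = kept$t_h, data = kept)
}

# Penalized iteratively-reweighted least squares for logistic regression.
# Objective: -(1/n) loglik + (lambda/2) ||beta||^2 (intercept unpenalized).
# Deterministic: cold start at beta = 0, Newton steps to 1e-10.
irls_logistic <- function(x, y, lambda = 1e-6, max_iter = 100, tol = 1e-10) {
  n <- nrow(x); p <- ncol(x)
  X <- cbind(`(intercept)` = 1, x)
  beta <- numeric(p + 1)
  pen <- diag(c(0, rep(lambda * n, p)), p + 1)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    beta <- drop(beta_new)
    mu <- plogis(drop(X %*% beta))
    dev <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu, 1e-300))) +
      lambda * n * sum(beta[-1]^2)
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) break
    dev_old <- dev
  }
  list(beta = beta, deviance = dev, iterations = it,
       converged = it < max_iter)
}

#' Fit the pooled logistic regression
#'
#' Features are z-scored with training means/SDs; the maximum-likelihood
#' logistic fit carries a weak L2 ridge (default strength negligible) so
#' that perfectly separated or collinear pooled rows still yield finite,
#' deterministic coefficients. Zero-variance features are dropped with a
#' warning. Coefficients are stored in standardized space together with the
#' standardization, so prediction is fully determined by the artifact.
#'
#' @param x Numeric design matrix (rows = (patient, time) observations).
#' @param y 0/1 outcome vector (1 = death within 30 days).
#' @param lambda Ridge strength; see [training_config()].
#' @return An object of class `icp_fit` with elements `intercept`, `weights`
#'   (standardized space), `center`, `scale`, `features`, `lambda`,
#'   `deviance`, `converged`, `nobs`.
#' @export
fit_logistic <- function(x, y, lambda = 1e-6) {
  stopifnot(is.matrix(x), nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) {
    stop_icpdyn("both outcome classes required to fit", "icpdyn_data_error")
  }
  if (anyNA(x)) stop_icpdyn("missing values in design matrix",
                            "icpdyn_data_error")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  drop_zv <- scl == 0 | !is.finite(scl)
  if (any(drop_zv)) {
    msg <- paste0("dropping zero-variance feature(s): ",
                  paste(colnames(x)[drop_zv], collapse = ", "))
    rlang::warn(msg, .frequency = "once", .frequency_id = msg)
  }
  keep <- !drop_zv
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  fit <- irls_logistic(z, y, lambda = lambda)
  structure(
    list(intercept = unname(fit$beta[1]),
         weights = setNames(fit$beta[-1], colnames(x)[keep]),
         center = ctr[keep], scale = scl[keep],
         features = colnames(x)[keep], dropped = colnames(x)[drop_zv],
         lambda = lambda, deviance = fit$deviance,
         iterations = fit$iterations, converged = fit$converged,
         nobs = length(y), prevalence = mean(y)),
    class = "icp_fit")
}

#' @export
print.icp_fit <- function(x, ...) {
  cat(sprintf("<icp_fit> %d features, n = %d, deviance = %.2f (lambda = %g)\n",
              length(x$weights), x$nobs, x$deviance, x$lambda))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted pooled logistic model
#'
#' One row per term. `estimate` is on the natural (mmHg etc.) scale;
#' `std_estimate` is the per-SD coefficient actually stored in the model
#' (the scale on which features are ranked for elimination).
#'
#' @param x An `icp_fit`.
#' @param ... Unused.
#' @method tidy icp_fit
#' @export
tidy.icp_fit <- function(x, ...) {
  nat <- x$weights / x$scale
  nat_int <- x$intercept - sum(x$weights * x$center / x$scale)
  tibble(term = c("(intercept)", names(x$weights)),
         estimate = c(nat_int, unname(nat)),
         std_estimate = c(x$intercept, unname(x$weights)))
}

#' @rdname tidy.icp_fit
#' @method glance icp_fit
#' @export
glance.icp_fit <- function(x, ...) {
  tibble(nobs = x$nobs, n_features = length(x$weights),
         deviance = x$deviance, lambda = x$lambda,
         prevalence = x$prevalence, converged = x$converged)
}

# risk for a feature matrix under an icp_fit; NA rows -> NA
fit_predict <- function(fit, x) {
  missing_cols <- setdiff(fit$features, colnames(x))
  if (length(missing_cols) > 0) {
    stop_icpdyn(paste0("features absent from new data: ",
                       paste(missing_cols, collapse = ", ")),
                "icpdyn_schema_error")
  }
  z <- sweep(sweep(x[, fit$features, drop = FALSE], 2, fit$center), 2,
             fit$scale, "/")
  unname(plogis(fit$intercept + drop(z %*% fit$weights)))
}

#' Stratified patient-level cross-validation folds
#'
#' Patients (not rows) are dealt into `k` folds, separately within each
#' outcome class after a seeded shuffle, so per-fold mortality prevalence
#' matches the cohort's to within one patient.
#'
#' @param patient_ids Unique patient identifiers.
#' @param outcomes 0/1 outcome per patient (same order).
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer fold assignment (1..k) per patient.
#' @export
stratified_group_folds <- function(patient_ids, outcomes, k, seed) {
  stopifnot(length(patient_ids) == length(outcomes),
            !anyDuplicated(patient_ids))
  if (min(table(outcomes)) < k) {
    stop_icpdyn(sprintf("too few patients in a class for %d folds", k),
                "icpdyn_data_error")
  }
  fold <- integer(length(patient_ids))
  set.seed(seed)
  for (cls in unique(outcomes)) {
    idx <- which(outcomes == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Elimination path: fit on all features, repeatedly drop the feature with the
# smallest |standardized coefficient|. Returns feature names in *keep
# priority* order: position 1 = eliminated last (strongest).
rfe_path <- function(x, y, lambda) {
  remaining <- colnames(x)
  order_out <- character(0)
  while (length(remaining) > 1) {
    fit <- fit_logistic(x[, remaining, drop = FALSE], y, lambda = lambda)
    w <- abs(fit$weights)
    # zero-variance features dropped by the fit are eliminated first
    gone <- setdiff(remaining, names(w))
    if (length(gone) == 0) gone <- names(w)[which.min(w)]
    order_out <- c(gone, order_out)
    remaining <- setdiff(remaining, gone)
  }
  c(remaining, order_out)
}

#' Recursive feature elimination with stratified patient-level CV
#'
#' Within each training fold the features are ranked by recursive
#' elimination (repeatedly refit, drop the feature with the smallest
#' absolute standardized coefficient); each candidate feature-count is scored
#' by the out-of-fold AUC of the model restricted to the fold's top features,
#' and the count with the highest mean CV AUC wins (ties break toward fewer
#' features). The returned subset is the full-data elimination path truncated
#' at the winning count. Fold randomization is seeded; different seeds may
#' select different subsets — both the seed and the per-count report are
#' returned.
#'
#' @param rows Output of [assemble_training_rows()].
#' @param config A [training_config()].
#' @return List with `selected` (ordered feature names), `n_selected`,
#'   `cv_report` (tibble: n_features, mean/sd out-of-fold AUC), `seed`,
#'   `path` (full-data elimination order).
#' @export
rfe_select <- function(rows, config = training_config()) {
  x <- rows$x; y <- rows$y; groups <- rows$groups
  p <- ncol(x)
  grid <- sort(unique(config$rfe_grid %||% seq_len(p)))
  grid <- grid[grid >= 1 & grid <= p]
  pt <- tibble(patient_id = groups, y = y) |> distinct()
  fold_of <- stratified_group_folds(pt$patient_id, pt$y, config$n_folds,
                                    seed = config$seed)
  names(fold_of) <- pt$patient_id
  row_fold <- fold_of[groups]

  scores <- matrix(NA_real_, nrow = length(grid), ncol = config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- row_fold != f
    path_f <- rfe_path(x[tr, , drop = FALSE], y[tr], config$lambda)
    for (gi in seq_along(grid)) {
      feats <- path_f[seq_len(grid[gi])]
      fit <- fit_logistic(x[tr, feats, drop = FALSE], y[tr],
                          lambda = config$lambda)
      pr <- fit_predict(fit, x[!tr, feats, drop = FALSE])
      scores[gi, f] <- roc_auc(pr, y[!tr])
    }
  }
  mean_auc <- rowMeans(scores, na.rm = TRUE)
  best <- grid[which.max(mean_auc)]   # which.max takes the first (fewest) tie
  full_path <- rfe_path(x, y, config$lambda)
  list(selected = full_path[seq_len(best)], n_selected = best,
       cv_report = tibble(n_features = grid, mean_cv_auc = mean_auc,
                          sd_cv_auc = apply(scores, 1, stats::sd)),
       seed = config$seed, path = full_path)
}

#' Fit the full dynamic model (RFE + final pooled fit)
#'
#' Runs [rfe_select()] on the pooled rows, then refits the pooled logistic
#' regression on the selected subset. The resulting coefficients are constant
#' across prediction times; risk varies over time only through the features.
#'
#' @param features An `icp_features` tibble from [featurize()].
#' @param config A [training_config()].
#' @param quiet Suppress messages.
#' @return An object of class `icp_model`: the final `icp_fit`, the selected
#'   features, the CV report and the configuration.
#' @export
fit_dynamic_model <- function(features, config = training_config(),
                              quiet = FALSE) {
  rows <- assemble_training_rows(features, quiet = quiet)
  sel <- rfe_select(rows, config)
  fit <- fit_logistic(rows$x[, sel$selected, drop = FALSE], rows$y,
                      lambda = config$lambda)
  inform_counts("fit_dynamic_model: selected ", sel$n_selected,
                " of ", ncol(rows$x), " candidate features (mean CV AUC ",
                sprintf("%.3f", max(sel$cv_report$mean_cv_auc)), ")",
                quiet = quiet)
  structure(list(fit = fit, selected = sel$selected,
                 cv_report = sel$cv_report, rfe_path = sel$path,
                 config = config,
                 grammar_hash = attr(features, "grammar_hash")),
            class = "icp_model")
}

#' @export
print.icp_model <- function(x, ...) {
  cat(sprintf("<icp_model> %d selected features (pooled logistic, lambda = %g)\n",
              length(x$selected), x$config$lambda))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidy.icp_fit
#' @method tidy icp_model
#' @export
tidy.icp_model <- function(x, ...) tidy(x$fit)

#' @rdname tidy.icp_fit
#' @method glance icp_model
#' @export
glance.icp_model <- function(x, ...) {
  dplyr::bind_cols(glance(x$fit),
                   tibble(best_cv_auc = max(x$cv_report$mean_cv_auc)))
}

#' Predict death risk on the 8-h schedule
#'
#' Applies a fitted model to a feature table. A (patient, time) row yields a
#' probability only when every selected feature is present; otherwise the
#' prediction is absent (`NA`) — the patient is excluded from that
#' time-point's estimate.
#'
#' @param model An `icp_model` (or bare `icp_fit`).
#' @param features An `icp_features` tibble.
#' @param check_hash Refuse to predict when the model's grammar hash differs
#'   from the feature table's (default `TRUE` when both are present).
#' @return Tibble `patient_id, t_h, probability` of class
#'   `icp_predictions`.
#' @export
predict_risk <- function(model, features, check_hash = TRUE) {
  fit <- if (inherits(model, "icp_model")) model$fit else model
  if (check_hash && inherits(model, "icp_model")) {
    fh <- attr(features, "grammar_hash")
    if (!is.null(fh) && !is.null(model$grammar_hash) &&
        !identical(fh, model$grammar_hash)) {
      stop_icpdyn("feature grammar hash does not match the model artifact",
                  "icpdyn_schema_error")
    }
  }
  missing_cols <- setdiff(fit$features, names(features))
  if (length(missing_cols) > 0) {
    stop_icpdyn(paste0("features absent from new data: ",
                       paste(missing_cols, collapse = ", ")),
                "icpdyn_schema_error")
  }
  x <- as.matrix(features[, fit$features, drop = FALSE])
  ok <- stats::complete.cases(x)
  prob <- rep(NA_real_, nrow(x))
  if (any(ok)) prob[ok] <- fit_predict(fit, x[ok, , drop = FALSE])
  out <- tibble(patient_id = features$patient_id, t_h = features$t_h,
                probability = prob)
  structure(out, class = c("icp_predictions", class(out)))
}

#' Dichotomize a death-risk probability
#'
#' `"death"` exactly when the probability strictly exceeds the threshold
#' (a predicted risk *higher than* 50% flags death; a tie at the threshold
#' classifies as survival).
#'
#' @param probability Probabilities in `[0, 1]` (NA allowed: propagated).
#' @param threshold Decision threshold in (0, 1); 0.25, 0.50 and 0.75 are
#'   the conventional settings.
#' @return Factor with levels `survival`, `death`.
#' @export
classify <- function(probability, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop_icpdyn("threshold must lie strictly inside (0, 1)")
  }
  if (any(probability < 0 | probability > 1, na.rm = TRUE)) {
    stop_icpdyn("probabilities must lie in [0, 1]")
  }
  factor(if_else(probability > threshold, "death", "survival"),
         levels = c("survival", "death"))
}

#' Internal cross-validation of the full training procedure
#'
#' Stratified patient-level k-fold CV of the *entire* pipeline: within each
#' training fold, recursive feature elimination (with its own inner CV) and a
#' pooled fit; held-out patients are scored at every scheduled time they have
#' complete features for. Per-fold metric curves are computed and averaged
#' across folds per time-point (the pooled-out-of-fold alternative is
#' returned as well).
#'
#' @param features An `icp_features` tibble.
#' @param config A [training_config()].
#' @param thresholds Decision thresholds for error-rate curves.
#' @param quiet Suppress messages.
#' @return An object of class `icp_cv`: `curves` (fold-averaged metric
#'   tibble), `pooled_curves` (metrics of pooled out-of-fold predictions),
#'   `fold_curves`, `predictions` (pooled out-of-fold), `selected` (per-fold
#'   feature lists), `config`.
#' @export
run_internal_cv <- function(features, config = training_config(),
                            thresholds = c(0.25, 0.5, 0.75), quiet = FALSE) {
  rows <- assemble_training_rows(features, quiet = quiet)
  pt <- tibble(patient_id = rows$groups, y = rows$y) |> distinct()
  fold_of <- stratified_group_folds(pt$patient_id, pt$y, config$n_folds,
                                    seed = config$seed)
  names(fold_of) <- pt$patient_id

  fold_preds <- list(); fold_selected <- list()
  for (f in seq_len(config$n_folds)) {
    tr_pat <- pt$patient_id[fold_of != f]
    tr <- rows$groups %in% tr_pat
    sub_rows <- list(x = rows$x[tr, , drop = FALSE], y = rows$y[tr],
                     groups = rows$groups[tr])
    inner_cfg <- config
    inner_cfg$seed <- config$seed * 1000L + f   # distinct inner fold shuffle
    sel <- rfe_select(sub_rows, inner_cfg)
    fit <- fit_logistic(rows$x[tr, sel$selected, drop = FALSE], rows$y[tr],
                        lambda = config$lambda)
    te <- !tr
    pr <- fit_predict(fit, rows$x[te, , drop = FALSE])
    fold_preds[[f]] <- tibble(fold = f,
                              patient_id = rows$groups[te],
                              t_h = rows$t_h[te],
                              probability = pr,
                              outcome = rows$y[te])
    fold_selected[[f]] <- sel$selected
    inform_counts("run_internal_cv: fold ", f, "/", config$n_folds, " — ",
                  length(sel$selected), " features", quiet = quiet)
  }
  preds <- bind_rows(fold_preds)
  outcomes <- distinct(preds, .data$patient_id, .data$outcome)

  fold_curves <- split(preds, preds$fold) |>
    purrr::map(function(fold_df) {
      # note: `fp` is a column of the metric table, so keep the fold id in a
      # plain local before mutate()'s data mask comes into scope
      fold_id <- fold_df$fold[1]
      mutate(metric_curves(select(fold_df, "patient_id", "t_h",
                                  "probability"),
                           distinct(fold_df, .data$patient_id,
                                    .data$outcome),
                           thresholds = thresholds),
             fold = fold_id)
    }) |>
    bind_rows()
  curves <- fold_curves |>
    group_by(.data$t_h, .data$threshold) |>
    summarise(across(c("auc", "auprc", "accuracy", "fp_rate", "fn_rate"),
                     ~ mean(.x, na.rm = TRUE)),
              n_evaluated = sum(.data$n_evaluated), n_folds = n(),
              .groups = "drop")
  pooled_curves <- metric_curves(
    select(preds, "patient_id", "t_h", "probability"), outcomes,
    thresholds = thresholds)

  structure(list(curves = curves, pooled_curves = pooled_curves,
                 fold_curves = fold_curves, predictions = preds,
                 selected = fold_selected, config = config),
            class = "icp_cv")
}

#' @export
print.icp_cv <- function(x, ...) {
  rng <- x$curves |> filter(.data$threshold == .data$threshold[1])
  cat(sprintf(
    "<icp_cv> %d-fold patient-level CV; fold-averaged AUC %.3f (%g h) -> %.3f (%g h)\n",
    x$config$n_folds,
    rng$auc[which.min(rng$t_h)], min(rng$t_h),
    rng$auc[which.max(rng$t_h)], max(rng$t_h)))
  invisible(x)
}

#' @rdname tidy.icp_fit
#' @method tidy icp_cv
#' @export
tidy.icp_cv <- function(x, ...) x$curves

#' @rdname tidy.icp_fit
#' @method glance icp_cv
#' @export
glance.icp_cv <- function(x, ...) {
  one <- filter(x$curves, .data$threshold == 0.5 |
                  .data$threshold == .data$threshold[1])
  tibble(n_folds = x$config$n_folds,
         auc_first = one$auc[which.min(one$t_h)],
         auc_last = one$auc[which.max(one$t_h)],
         auprc_first = one$auprc[which.min(one$t_h)],
         auprc_last = one$auprc[which.max(one$t_h)])
}

#' Save / load a model artifact as JSON
#'
#' The artifact carries a schema version, the feature-grammar hash, selected
#' features, standardized coefficients with their standardization, the
#' training configuration and seed, and the RFE CV report — everything needed
#' for deterministic prediction.
#'
#' @param model An `icp_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_model()` returns the `icp_model`.
#' @export
write_model <- function(model, path) {
  obj <- list(
    schema_version = 1L,
    grammar_hash = model$grammar_hash,
    selected = model$selected,
    intercept = model$fit$intercept,
    weights = as.list(model$fit$weights),
    center = as.list(model$fit$center),
    scale = as.list(model$fit$scale),
    lambda = model$fit$lambda,
    nobs = model$fit$nobs,
    prevalence = model$fit$prevalence,
    config = unclass(model$config),
    cv_report = model$cv_report,
    rfe_path = model$rfe_path
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(obj$schema_version), 1L)) {
    stop_icpdyn("unsupported model schema version", "icpdyn_schema_error")
  }
  fit <- structure(
    list(intercept = obj$intercept,
         weights = unlist(obj$weights),
         center = unlist(obj$center),
         scale = unlist(obj$scale),
         features = obj$selected,
         lambda = obj$lambda, nobs = obj$nobs,
         prevalence = obj$prevalence, converged = TRUE,
         deviance = NA_real_),
    class = "icp_fit")
  cfg <- obj$config
  structure(list(fit = fit, selected = obj$selected,
                 cv_report = as_tibble(obj$cv_report),
                 rfe_path = obj$rfe_path,
                 config = training_config(n_folds = cfg$n_folds,
                                          rfe_grid = cfg$rfe_grid,
                                          seed = cfg$seed,
                                          lambda = cfg$lambda,
                                          pooling = cfg$pooling),
                 grammar_hash = obj$grammar_hash),
            class = "icp_model")
}
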
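# Time-dependent evaluation.
#
# All metrics at a prediction time t are computed over the patients who
# *have* a prediction at t; patients whose windows were missing or whose
# monitoring had ended are excluded from that time-point, so the evaluated-n
# is always reported alongside the metrics (the evaluated population drifts
# toward long-monitored patients at late t).
#
# fp_rate / fn_rate follow the predictive-value convention: the share of
# predicted deaths who survived (1 - precision; a false-discovery
# proportion) and the share of predicted survivors who died (false-omission
# proportion). The classic fp/(fp+tn), fn/(fn+tp) convention is available
# via `convention = "classic"`.

#' Confusion counts at one prediction time
#'
#' Positive class = death. A patient is a false positive when the predicted
#' death risk strictly exceeds the threshold but they survived, and a false
#' negative when the risk was at or below the threshold but they died.
#'
#' @param predictions Tibble `patient_id, t_h, probability`
#'   (e.g. from [predict_risk()]); `NA` probabilities are excluded.
#' @param outcomes Tibble `patient_id, outcome` (1 = death).
#' @param t_h Prediction time in hours.
#' @param threshold Decision threshold, strict `>` rule.
#' @return One-row tibble `t_h, threshold, tp, fp, fn, tn, n_evaluated`.
#' @export
confusion_at <- function(predictions, outcomes, t_h, threshold = 0.5) {
  ev <- evaluated_at(predictions, outcomes, t_h)
  cls <- classify(ev$probability, threshold)
  tibble(
    t_h = t_h, threshold = threshold,
    tp = sum(cls == "death" & ev$outcome == 1),
    fp = sum(cls == "death" & ev$outcome == 0),
    fn = sum(cls == "survival" & ev$outcome == 1),
    tn = sum(cls == "survival" & ev$outcome == 0),
    n_evaluated = nrow(ev)
  )
}

evaluated_at <- function(predictions, outcomes, t_h) {
  assert_columns(predictions, c("patient_id", "t_h", "probability"),
                 "predictions")
  assert_columns(outcomes, c("patient_id", "outcome"), "outcomes")
  predictions |>
    filter(.data$t_h == !!t_h, !is.na(.data$probability)) |>
    inner_join(distinct(outcomes, .data$patient_id, .data$outcome),
               by = "patient_id")
}

#' False-positive and false-negative proportions
#'
#' `fp_rate = fp / (fp + tp)`: of the patients the algorithm flagged as
#' dying, the share who survived. `fn_rate = fn / (fn + tn)`: of the
#' patients predicted to survive, the share who died. Degenerate
#' denominators (no predicted deaths / no predicted survivors) give `NA`.
#'
#' @param counts A row from [confusion_at()] (vectorized over rows).
#' @param convention `"predictive"` (default, above) or `"classic"`
#'   (`fp/(fp+tn)`, `fn/(fn+tp)`).
#' @return `counts` with `fp_rate` and `fn_rate` columns appended.
#' @export
fp_fn_rates <- function(counts, convention = c("predictive", "classic")) {
  convention <- match.arg(convention)
  if (convention == "predictive") {
    mutate(counts,
           fp_rate = if_else(.data$fp + .data$tp > 0,
                             .data$fp / (.data$fp + .data$tp), NA_real_),
           fn_rate = if_else(.data$fn + .data$tn > 0,
                             .data$fn / (.data$fn + .data$tn), NA_real_))
  } else {
    mutate(counts,
           fp_rate = if_else(.data$fp + .data$tn > 0,
                             .data$fp / (.data$fp + .data$tn), NA_real_),
           fn_rate = if_else(.data$fn + .data$tp > 0,
                             .data$fn / (.data$fn + .data$tp), NA_real_))
  }
}

#' Precision, recall and accuracy from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `accuracy = (tp+tn)/(tp+fp+fn+tn)`; degenerate denominators give `NA`.
#' Note `precision = 1 - fp_rate` under the predictive convention.
#'
#' @inheritParams fp_fn_rates
#' @return `counts` with `precision`, `recall`, `accuracy` appended.
#' @export
precision_recall_accuracy <- function(counts) {
  mutate(counts,
         precision = if_else(.data$tp + .data$fp > 0,
                             .data$tp / (.data$tp + .data$fp), NA_real_),
         recall = if_else(.data$tp + .data$fn > 0,
                          .data$tp / (.data$tp + .data$fn), NA_real_),
         accuracy = (.data$tp + .data$tn) /
           (.data$tp + .data$fp + .data$fn + .data$tn))
}

#' Concordance AUC of scores against binary outcomes
#'
#' Probability that a randomly chosen patient who died received a higher
#' score than a randomly chosen survivor, ties counted half — computed via
#' mid-ranks (Mann-Whitney), identical to the brute-force mean over all
#' (dead, alive) pairs.
#'
#' @param scores Numeric scores (no NA).
#' @param labels 0/1 outcomes, 1 = death.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when a class is absent.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    rlang::warn("AUC undefined: only one outcome class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) area: thresholds sweep the unique score
#' values in descending order, tied scores enter together, and each recall
#' increment contributes at the precision attained at that threshold
#' (average precision with tie grouping). A constant scorer therefore scores
#' the positive prevalence; linear PR interpolation is deliberately avoided
#' as optimistic.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `[0, 1]`, `NA` (with a warning) when no positives.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) {
    rlang::warn("AUPRC undefined: no positives present")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y == 1)
  cum_pp <- seq_along(y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)  # threshold = each unique score
  tp <- cum_tp[last_of_tie]
  pp <- cum_pp[last_of_tie]
  precision <- tp / pp
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' @rdname roc_auc
#' @param predictions,outcomes,t_h As in [confusion_at()].
#' @details `auc_at()` / `auprc_at()` evaluate the metric over the patients
#'   with a prediction at `t_h`.
#' @export
auc_at <- function(predictions, outcomes, t_h) {
  ev <- evaluated_at(predictions, outcomes, t_h)
  roc_auc(ev$probability, ev$outcome)
}

#' @rdname roc_auc
#' @export
auprc_at <- function(predictions, outcomes, t_h) {
  ev <- evaluated_at(predictions, outcomes, t_h)
  pr_auc(ev$probability, ev$outcome)
}

#' Time-dependent metric curves
#'
#' Assembles, for every prediction time present and every threshold, the
#' confusion counts, fp/fn proportions, precision/recall/accuracy, AUC and
#' AUPRC, together with the number of evaluated patients.
#'
#' @param predictions Tibble `patient_id, t_h, probability`.
#' @param outcomes Tibble `patient_id, outcome`.
#' @param thresholds Decision thresholds; default `c(0.25, 0.5, 0.75)`.
#' @param convention fp/fn-rate convention, see [fp_fn_rates()].
#' @return Tibble of class `icp_metric_curves`:
#'   `t_h, threshold, n_evaluated, auc, auprc, accuracy, fp_rate, fn_rate,
#'   precision, recall, tp, fp, fn, tn`.
#' @export
metric_curves <- function(predictions, outcomes,
                          thresholds = c(0.25, 0.5, 0.75),
                          convention = c("predictive", "classic")) {
  convention <- match.arg(convention)
  t_hs <- sort(unique(predictions$t_h[!is.na(predictions$probability)]))
  rows <- tidyr::expand_grid(t_h = t_hs, threshold = thresholds)
  disc <- purrr::map(t_hs, function(t) {
    ev <- evaluated_at(predictions, outcomes, t)
    both <- length(unique(ev$outcome)) == 2
    tibble(t_h = t,
           auc = if (both) roc_auc(ev$probability, ev$outcome) else NA_real_,
           auprc = if (any(ev$outcome == 1))
             pr_auc(ev$probability, ev$outcome) else NA_real_)
  }) |> bind_rows()
  out <- purrr::pmap(rows, function(t_h, threshold) {
    confusion_at(predictions, outcomes, t_h, threshold)
  }) |>
    bind_rows() |>
    fp_fn_rates(convention = convention) |>
    precision_recall_accuracy() |>
    left_join(disc, by = "t_h") |>
    select("t_h", "threshold", "n_evaluated", "auc", "auprc", "accuracy",
           "fp_rate", "fn_rate", "precision", "recall",
           "tp", "fp", "fn", "tn")
  structure(out, class = c("icp_metric_curves", class(out)))
}

#' Write metric curves to CSV
#'
#' @param curves An `icp_metric_curves` tibble.
#' @param path Output path.
#' @export
write_metric_curves <- function(curves, path) {
  readr::write_csv(curves, path, na = "")
  invisible(path)
}
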
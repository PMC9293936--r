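# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline facet_wrap labs scale_color_brewer coord_flip theme_minimal
#' @export
ggplot2::autoplot

#' Plot vitals for one patient
#'
#' Minute-gridded ICP/MAP/CPP traces against hours since admission; useful
#' for eyeballing artifacts, missing blocks and the non-survivor ICP drift.
#'
#' @param vitals Long tibble `patient_id, time_min, signal, value`.
#' @param patient_id Patient to show.
#' @return A ggplot.
#' @export
plot_vitals <- function(vitals, patient_id) {
  df <- filter(vitals, .data$patient_id == !!patient_id)
  ggplot(df, aes(.data$time_min / 60, .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~ toupper(signal), ncol = 1, scales = "free_y") +
    labs(x = "hours since admission", y = "mmHg",
         title = paste("patient", patient_id)) +
    theme_minimal()
}

#' @rdname autoplot-icpdyn
#' @method autoplot icp_metric_curves
#' @export
autoplot.icp_metric_curves <- function(object, metrics = c("auc", "auprc",
                                                           "accuracy",
                                                           "fp_rate",
                                                           "fn_rate"), ...) {
  df <- object |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
    mutate(threshold = factor(.data$threshold))
  ggplot(df, aes(.data$t_h, .data$value, colour = .data$threshold)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~ metric, scales = "free_y") +
    labs(x = "prediction time (h)", y = NULL, colour = "threshold") +
    theme_minimal()
}

#' Autoplot methods for icpdyn result objects
#'
#' `icp_metric_curves`: each metric against prediction time, one line per
#' decision threshold. `icp_cv`: the fold-averaged curves. `icp_model`:
#' selected features ranked by absolute standardized coefficient, colour =
#' direction (red: higher value raises death risk; blue: lowers it).
#'
#' @param object The result object.
#' @param metrics Metric columns to draw (curve plots).
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-icpdyn
#' @method autoplot icp_cv
#' @export
autoplot.icp_cv <- function(object, metrics = c("auc", "auprc", "fp_rate",
                                                "fn_rate"), ...) {
  autoplot.icp_metric_curves(object$curves, metrics = metrics)
}

#' @rdname autoplot-icpdyn
#' @method autoplot icp_model
#' @export
autoplot.icp_model <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$term != "(intercept)") |>
    mutate(direction = if_else(.data$std_estimate > 0,
                               "raises death risk", "lowers death risk"),
           term = stats::reorder(.data$term, abs(.data$std_estimate)))
  ggplot(df, aes(.data$term, abs(.data$std_estimate),
                 fill = .data$direction)) +
    geom_col() + coord_flip() +
    ggplot2::scale_fill_manual(values = c("raises death risk" = "#b2182b",
                                          "lowers death risk" = "#2166ac")) +
    labs(x = NULL, y = "|standardized coefficient|", fill = NULL) +
    theme_minimal()
}
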
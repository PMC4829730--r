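# ggplot2 helpers for the two result types users inspect most: the
# across-participant performance summary and the incremental assessment.

#' Plot per-participant predictive performance
#'
#' Dot-plus-interval plot of a performance metric by model family (one dot
#' per participant, the across-participant mean with a 95% CI overlaid),
#' faceted by measure.
#'
#' @param performance Output of [participant_performance()].
#' @param metric `"cv_mse"` or `"pct_correct"`.
#' @return A ggplot object.
#' @export
plot_performance <- function(performance, metric = c("cv_mse", "pct_correct")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(performance,
                  ggplot2::aes(x = .data$family, y = .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.4, size = 1) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se,
                          fun.args = list(mult = 1.96),
                          geom = "pointrange", colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure)) +
    ggplot2::labs(x = NULL,
                  y = if (metric == "cv_mse") "cross-validated MSE"
                      else "% correct (within margin)") +
    ggplot2::theme_minimal()
}

#' Plot the incremental assessment
#'
#' Shows, per model family, the day-by-day difference to the mean-model
#' benchmark (positive MSE difference = personalized model worse) as the
#' training window grows.
#'
#' @param object A `mood_incremental` from [incremental_evaluate()].
#' @param metric `"mse"` or `"pct_correct"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mood_incremental
#' @export
autoplot.mood_incremental <- function(object, metric = c("mse", "pct_correct"),
                                      ...) {
  metric <- match.arg(metric)
  ref <- object$daily |>
    dplyr::filter(.data$family == "mean") |>
    dplyr::select("day_index", ref = dplyr::all_of(metric))
  df <- object$daily |>
    dplyr::filter(.data$family != "mean") |>
    dplyr::inner_join(ref, by = "day_index") |>
    dplyr::mutate(diff = .data[[metric]] - .data$ref)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day_index, y = .data$diff,
                                   colour = .data$family)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "study day",
                  y = sprintf("%s difference to mean model", metric),
                  title = sprintf("Incremental performance (%s)", object$measure)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
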
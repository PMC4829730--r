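# Evaluation framework: full-data leave-one-out assessment of each model
# family (with variable selection rerun inside every fold), paired Wilcoxon
# signed-rank benchmark comparisons across participants, and the incremental
# growing-training-window assessment with its trend regression.

model_families <- function() c("mean", "history", "stepAIC", "stepCV")

fit_family <- function(data, target, family, cap_divisor = 5) {
  switch(family,
         mean = fit_mean_model(data, target),
         history = fit_history_model(data, target),
         stepAIC = forward_select_aic(
           data, target, cap_variables(nrow(data), cap_divisor)),
         stepCV = forward_select_cv(
           data, target, cap_variables(nrow(data), cap_divisor)),
         rlang::abort(sprintf("unknown model family: %s", family)))
}

min_rows_for <- function(family) {
  switch(family, mean = 2L, history = 4L, 3L)
}

table_measure <- function(features) {
  m <- attr(features, "measure")
  if (is.null(m)) NA_character_ else m
}

#' Leave-one-out evaluation of one model family
#'
#' For every modelable day of every participant, reruns the entire fitting
#' procedure for `family` — including forward variable selection for the
#' stepwise families — on all of that participant's other modelable days,
#' then predicts the held-out day. A prediction is "correct" when its
#' absolute error on the standardized scale is at most `margin`
#' (inclusive). Participants with fewer than 4 modelable rows are skipped
#' with a warning.
#'
#' @param features Feature table from [build_feature_table()].
#' @param family One of `"mean"`, `"history"`, `"stepAIC"`, `"stepCV"`.
#' @param margin Tolerated error margin on the standardized scale.
#' @param cap_divisor Training points per admitted variable
#'   ([cap_variables()]).
#' @return Tibble of prediction records: `participant_id`, `day_index`,
#'   `measure`, `family`, `observed_z`, `predicted_z`, `abs_error`,
#'   `correct`.
#' @export
loocv_evaluate <- function(features, family, margin = 0.5, cap_divisor = 5) {
  measure <- table_measure(features)
  rows <- features[features$modelable, , drop = FALSE]
  out <- list()
  for (pid in unique(rows$participant_id)) {
    d <- rows[rows$participant_id == pid, , drop = FALSE]
    if (nrow(d) < 4) {
      rlang::warn(sprintf(
        "participant %s has %d modelable day(s) (< 4); skipped", pid, nrow(d)))
      next
    }
    pred <- vapply(seq_len(nrow(d)), function(i) {
      m <- fit_family(d[-i, , drop = FALSE], "target", family, cap_divisor)
      predict(m, d[i, , drop = FALSE])
    }, numeric(1))
    out[[pid]] <- tibble::tibble(participant_id = pid,
                                 day_index = d$day_index,
                                 measure = measure, family = family,
                                 observed_z = d$target, predicted_z = pred)
  }
  finish_predictions(out, margin)
}

empty_predictions <- function() {
  tibble::tibble(participant_id = character(0), day_index = integer(0),
                 measure = character(0), family = character(0),
                 observed_z = numeric(0), predicted_z = numeric(0))
}

finish_predictions <- function(out, margin) {
  tbl <- if (length(out)) purrr::list_rbind(out) else empty_predictions()
  dplyr::mutate(tbl,
                abs_error = abs(.data$observed_z - .data$predicted_z),
                correct = .data$abs_error <= margin)
}

#' Per-participant performance summary
#'
#' Aggregates prediction records to one row per participant, measure and
#' family: the cross-validated MSE (mean of squared held-out residuals) and
#' the percentage of predictions within the tolerated error margin.
#'
#' @param predictions Prediction records from [loocv_evaluate()] or the
#'   `predictions` element of [incremental_evaluate()] (families may be
#'   stacked).
#' @return Tibble: `participant_id`, `measure`, `family`, `cv_mse`,
#'   `pct_correct`, `n_predictions`.
#' @export
participant_performance <- function(predictions) {
  predictions |>
    dplyr::group_by(.data$participant_id, .data$measure, .data$family) |>
    dplyr::summarise(
      cv_mse = mean((.data$observed_z - .data$predicted_z)^2),
      pct_correct = 100 * mean(.data$correct),
      n_predictions = dplyr::n(), .groups = "drop")
}

# Two-sided Wilcoxon signed-rank on paired differences. Zeros dropped;
# exact distribution for <= `exact_max` untied pairs, otherwise normal
# approximation with tie correction and continuity correction.
wilcoxon_signed_rank <- function(d, exact_max = 12) {
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n_pairs = 0L,
                degenerate = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= exact_max && !ties) {
    p <- min(1, 2 * min(stats::psignrank(V, n),
                        stats::psignrank(V - 1, n, lower.tail = FALSE)))
  } else {
    mu <- n * (n + 1) / 4
    cnt <- as.numeric(table(abs(d)))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(cnt^3 - cnt) / 48
    if (sigma2 <= 0)
      return(list(statistic = V, p_value = 1, n_pairs = n, degenerate = TRUE))
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = V, p_value = p, n_pairs = n, degenerate = FALSE)
}

#' Compare two model families across participants
#'
#' Paired two-sided Wilcoxon signed-rank test on the per-participant values
#' of a performance metric for two families (pairs matched by participant
#' within each measure). All-zero differences yield a degenerate result
#' with p = 1.
#'
#' @param performance Output of [participant_performance()] containing both
#'   families.
#' @param family_a,family_b Family names to compare.
#' @param metric `"cv_mse"` or `"pct_correct"`.
#' @return Tibble, one row per measure: `family_a`, `family_b`, `measure`,
#'   `metric`, `statistic`, `p_value`, `n_pairs`, `degenerate`,
#'   `median_diff` (median of a - b).
#' @export
compare_families <- function(performance, family_a, family_b,
                             metric = c("cv_mse", "pct_correct")) {
  metric <- match.arg(metric)
  wide <- performance |>
    dplyr::filter(.data$family %in% c(family_a, family_b)) |>
    dplyr::select(dplyr::all_of(c("participant_id", "measure", "family",
                                  metric))) |>
    tidyr::pivot_wider(names_from = "family",
                       values_from = dplyr::all_of(metric))
  wide |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(function(g, key) {
      diff <- g[[family_a]] - g[[family_b]]
      w <- wilcoxon_signed_rank(diff)
      tibble::tibble(family_a = family_a, family_b = family_b,
                     metric = metric, statistic = w$statistic,
                     p_value = w$p_value, n_pairs = w$n_pairs,
                     degenerate = w$degenerate,
                     median_diff = stats::median(diff))
    }) |>
    dplyr::ungroup()
}

#' Incremental (growing-training-window) evaluation
#'
#' Emulates deployment: for each day d from `start_day` to the end of the
#' study, each family is trained on the participant's modelable days
#' strictly before d and predicts day d (if that day is itself modelable).
#' Per-day metrics are aggregated across participants, and for each
#' personalized family the difference to the mean model (per day) is
#' regressed on an intercept and the study day, giving the trend estimates
#' and their standard errors.
#'
#' @inheritParams loocv_evaluate
#' @param families Families to run (the mean model is always included as
#'   the reference).
#' @param start_day First day used as a prediction target; earlier days
#'   only ever provide training data.
#' @return A `mood_incremental` list: `predictions` (per participant-day),
#'   `daily` (per family-day metrics across participants), `trend` (per
#'   family and metric: intercept/slope estimates and SEs).
#' @export
incremental_evaluate <- function(features, families = model_families(),
                                 margin = 0.5, start_day = 8,
                                 cap_divisor = 5) {
  measure <- table_measure(features)
  families <- union(families, "mean")
  n_days <- max(features$day_index)
  rows <- features[features$modelable, , drop = FALSE]
  out <- list()
  for (pid in unique(rows$participant_id)) {
    d <- rows[rows$participant_id == pid, , drop = FALSE]
    for (day in intersect(start_day:n_days, d$day_index)) {
      train <- d[d$day_index < day, , drop = FALSE]
      test <- d[d$day_index == day, , drop = FALSE]
      for (family in families) {
        if (nrow(train) < min_rows_for(family)) next
        m <- fit_family(train, "target", family, cap_divisor)
        p <- predict(m, test)
        out[[length(out) + 1]] <- tibble::tibble(
          participant_id = pid, day_index = day, measure = measure,
          family = family, n_train = nrow(train),
          observed_z = test$target, predicted_z = p)
      }
    }
  }
  predictions <- finish_predictions(out, margin)
  daily <- predictions |>
    dplyr::group_by(.data$family, .data$day_index) |>
    dplyr::summarise(mse = mean((.data$observed_z - .data$predicted_z)^2),
                     pct_correct = 100 * mean(.data$correct),
                     n = dplyr::n(), .groups = "drop")
  trend <- incremental_trend(daily, measure)
  structure(list(predictions = predictions, daily = daily, trend = trend,
                 measure = measure),
            class = "mood_incremental")
}

# per-day difference to the mean model, regressed on intercept + study day
incremental_trend <- function(daily, measure) {
  ref <- daily |>
    dplyr::filter(.data$family == "mean") |>
    dplyr::select("day_index", ref_mse = "mse", ref_pct = "pct_correct")
  rows <- list()
  for (fam in setdiff(unique(daily$family), "mean")) {
    joined <- daily |>
      dplyr::filter(.data$family == fam) |>
      dplyr::inner_join(ref, by = "day_index")
    for (metric in c("mse", "pct_correct")) {
      diff <- if (metric == "mse") joined$mse - joined$ref_mse
              else joined$pct_correct - joined$ref_pct
      # tiny or degenerate day sets can fit perfectly; the SEs are still
      # the standard OLS ones (possibly 0)
      fit <- suppressWarnings(
        summary(stats::lm(diff ~ joined$day_index)))$coefficients
      rows[[length(rows) + 1]] <- tibble::tibble(
        measure = measure, family = fam, metric = metric,
        intercept_estimate = fit[1, 1], intercept_se = fit[1, 2],
        slope_estimate = fit[2, 1], slope_se = fit[2, 2],
        n_days = nrow(joined))
    }
  }
  purrr::list_rbind(rows)
}

#' @export
print.mood_incremental <- function(x, ...) {
  cat("<mood_incremental> measure", x$measure, "-",
      nrow(x$predictions), "predictions over days",
      min(x$daily$day_index), "to", max(x$daily$day_index), "\n")
  print(x$trend)
  invisible(x)
}

#' Summary report across participants
#'
#' Collects, per measure and family, the across-participant mean
#' cross-validated MSE and mean percentage correct with normal-approximation
#' 95% confidence intervals (mean +/- 1.96 SE; undefined with a single
#' participant and flagged `NA`), alongside the benchmark comparison tests
#' and the incremental trend table.
#'
#' @param performance Output of [participant_performance()].
#' @param comparisons Optional stacked output of [compare_families()].
#' @param incremental Optional list of `mood_incremental` objects (or their
#'   stacked `trend` tibbles).
#' @return A `mood_report` list: `performance_table`, `comparisons`,
#'   `incremental_trend`.
#' @export
summarize_report <- function(performance, comparisons = NULL,
                             incremental = NULL) {
  ci <- function(x) 1.96 * stats::sd(x) / sqrt(length(x))
  tab <- performance |>
    dplyr::group_by(.data$measure, .data$family) |>
    dplyr::summarise(n_participants = dplyr::n(),
                     mean_pct_correct = mean(.data$pct_correct),
                     pct_correct_lo = mean_pct_correct - ci(.data$pct_correct),
                     pct_correct_hi = mean_pct_correct + ci(.data$pct_correct),
                     mean_cv_mse = mean(.data$cv_mse),
                     cv_mse_lo = mean_cv_mse - ci(.data$cv_mse),
                     cv_mse_hi = mean_cv_mse + ci(.data$cv_mse),
                     .groups = "drop")
  trend <- NULL
  if (!is.null(incremental)) {
    trend <- purrr::list_rbind(lapply(
      if (inherits(incremental, "mood_incremental")) list(incremental)
      else incremental,
      function(x) if (inherits(x, "mood_incremental")) x$trend else x))
  }
  structure(list(performance_table = tab, comparisons = comparisons,
                 incremental_trend = trend),
            class = "mood_report")
}

#' @export
print.mood_report <- function(x, ...) {
  cat("== Predictive performance (across participants) ==\n")
  print(x$performance_table, n = Inf)
  if (!is.null(x$comparisons)) {
    cat("\n== Benchmark comparisons (Wilcoxon signed-rank) ==\n")
    print(x$comparisons, n = Inf)
  }
  if (!is.null(x$incremental_trend)) {
    cat("\n== Incremental trend (difference to mean model) ==\n")
    print(x$incremental_trend, n = Inf)
  }
  invisible(x)
}
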
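# Prediction targets: mood-diary ratings aggregated to daily averages and
# standardized within each participant, plus adherence accounting and the
# 20-complete-days pruning rule.

rating_scales <- function() {
  list(mood = c(1, 10), valence = c(-2, 2), arousal = c(-2, 2))
}

# calendar day of a timestamp relative to study day 1 (day boundaries at
# local midnight; the pipeline works in UTC throughout)
day_of <- function(timestamp, study_start) {
  as.integer(as.Date(timestamp, tz = "UTC") - as.Date(study_start)) + 1L
}

#' Aggregate mood ratings to daily averages
#'
#' Collapses the (up to five per day) diary ratings to per participant-day
#' arithmetic means of the one-dimensional mood score and the circumplex
#' valence/arousal scores. Days with no ratings produce no row; they are
#' absent, never zero-filled. A rating belongs to the calendar day of its
#' timestamp.
#'
#' @param ratings Tibble with columns `participant_id`, `timestamp`
#'   (POSIXct), `mood` (1--10), `valence`, `arousal` (-2..2).
#' @param study_start Date of study day 1; defaults to the earliest rating
#'   date in the data.
#' @return Tibble: `participant_id`, `day_index`, `n_ratings`, `mean_mood`,
#'   `mean_valence`, `mean_arousal`.
#' @export
aggregate_daily <- function(ratings, study_start = NULL) {
  sc <- rating_scales()
  for (m in names(sc)) {
    bad <- which(is.na(ratings[[m]]) | ratings[[m]] < sc[[m]][1] |
                   ratings[[m]] > sc[[m]][2])
    if (length(bad))
      rlang::abort(sprintf(
        "rating outside scale bounds: %s = %s (participant %s, row %d)",
        m, format(ratings[[m]][bad[1]]), ratings$participant_id[bad[1]], bad[1]),
        class = "moodstep_validation_error")
  }
  if (is.null(study_start)) study_start <- min(as.Date(ratings$timestamp, tz = "UTC"))
  ratings |>
    dplyr::mutate(day_index = day_of(.data$timestamp, study_start)) |>
    dplyr::group_by(.data$participant_id, .data$day_index) |>
    dplyr::summarise(n_ratings = dplyr::n(),
                     mean_mood = mean(.data$mood),
                     mean_valence = mean(.data$valence),
                     mean_arousal = mean(.data$arousal),
                     .groups = "drop") |>
    dplyr::arrange(.data$participant_id, .data$day_index)
}

#' Standardize daily targets within participant
#'
#' Adds z-scored columns: each participant's daily means are centred on that
#' participant's mean and divided by that participant's sample standard
#' deviation (denominator n - 1), computed over all of their present days.
#' Participants with fewer than two days or a constant series on any
#' measure cannot be standardized; they are dropped with a warning naming
#' them.
#'
#' @param daily Output of [aggregate_daily()].
#' @return The input with `z_mood`, `z_valence`, `z_arousal` added;
#'   degenerate participants removed. The dropped ids are attached as
#'   attribute `"degenerate"`.
#' @export
standardize_targets <- function(daily) {
  stats_tbl <- daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_days = dplyr::n(),
                     dplyr::across(dplyr::starts_with("mean_"),
                                   list(mu = mean, sd = stats::sd)),
                     .groups = "drop")
  degen <- stats_tbl |>
    dplyr::filter(.data$n_days < 2 |
                    .data$mean_mood_sd == 0 | .data$mean_valence_sd == 0 |
                    .data$mean_arousal_sd == 0 |
                    is.na(.data$mean_mood_sd)) |>
    dplyr::pull(.data$participant_id)
  if (length(degen))
    rlang::warn(paste0("degenerate (constant or single-day) mood series; ",
                       "excluding participant(s): ",
                       paste(degen, collapse = ", ")))
  out <- daily |>
    dplyr::filter(!(.data$participant_id %in% degen)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(z_mood = (.data$mean_mood - mean(.data$mean_mood)) /
                    stats::sd(.data$mean_mood),
                  z_valence = (.data$mean_valence - mean(.data$mean_valence)) /
                    stats::sd(.data$mean_valence),
                  z_arousal = (.data$mean_arousal - mean(.data$mean_arousal)) /
                    stats::sd(.data$mean_arousal)) |>
    dplyr::ungroup()
  attr(out, "degenerate") <- degen
  out
}

#' Adherence accounting and participant pruning
#'
#' A participant-day is "complete" when it has both a mood target and a
#' modelable feature row (all predictors, including the two mood-history
#' lags, computable). Participants with fewer than `min_days` complete days
#' are excluded from modeling, mirroring the pruning applied before any
#' model fitting.
#'
#' @param targets Standardized daily targets ([standardize_targets()]).
#' @param features Feature table ([build_feature_table()]) carrying the
#'   `modelable` flag.
#' @param min_days Minimum number of complete days for inclusion; a
#'   participant with exactly `min_days` complete days is retained.
#' @return Tibble with one row per participant in `targets`:
#'   `participant_id`, `days_with_any_rating`, `days_with_4plus`,
#'   `last_day_rated`, `complete_days`, `included`.
#' @export
prune_participants <- function(targets, features, min_days = 20) {
  adherence <- targets |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(days_with_any_rating = dplyr::n(),
                     days_with_4plus = sum(.data$n_ratings >= 4),
                     last_day_rated = max(.data$day_index),
                     .groups = "drop")
  complete <- features |>
    dplyr::filter(.data$modelable) |>
    dplyr::semi_join(targets, by = c("participant_id", "day_index")) |>
    dplyr::count(.data$participant_id, name = "complete_days")
  adherence |>
    dplyr::left_join(complete, by = "participant_id") |>
    dplyr::mutate(complete_days = dplyr::coalesce(.data$complete_days, 0L),
                  included = .data$complete_days >= min_days)
}
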
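# Daily feature engineering: the six raw event streams of one participant
# become one 53-variable row per study day (see feature_schema()), plus
# lag-1/lag-2 mood history taken from the standardized targets.
#
# Histogram features share one mechanism: per-day weights for a fixed slot
# vocabulary, a trailing window sum (default 3 days, ending on the day being
# predicted), and sum-to-one normalization with the all-zero window mapping
# to all zeros.

add_day_index <- function(events, study_start, time_col = "timestamp") {
  events$day_index <- day_of(events[[time_col]], study_start)
  events
}

# n_days x length(slots) matrix of per-day summed weights
daily_weight_matrix <- function(day, slot, weight, slots, n_days) {
  W <- matrix(0, n_days, length(slots),
              dimnames = list(NULL, slots))
  if (length(day)) {
    keep <- !is.na(slot) & slot %in% slots & day >= 1 & day <= n_days
    if (any(keep)) {
      key <- (match(slot[keep], slots) - 1L) * n_days + day[keep]
      agg <- rowsum(weight[keep], key)
      W[as.integer(rownames(agg))] <- agg
    }
  }
  W
}

# trailing `window`-day sums per column: row d covers days max(1, d-w+1)..d
roll_window_sum <- function(W, window) {
  C <- apply(W, 2, cumsum)
  if (is.null(dim(C))) C <- matrix(C, ncol = ncol(W))
  n <- nrow(W)
  lag <- rbind(matrix(0, min(window, n), ncol(W)),
               C[seq_len(max(0, n - window)), , drop = FALSE])
  C - lag
}

normalize_rows <- function(S) {
  tot <- rowSums(S)
  out <- S / ifelse(tot > 0, tot, 1)
  out[tot == 0, ] <- 0
  out
}

hist_block <- function(day, slot, weight, slots, n_days, window, prefix) {
  M <- normalize_rows(roll_window_sum(
    daily_weight_matrix(day, slot, weight, slots, n_days), window))
  colnames(M) <- paste0(prefix, seq_along(slots))
  M
}

#' Rank a participant's top-5 entities by interaction count
#'
#' Entities (contacts or apps) are ranked by their total number of events
#' over the full study, so slot identity is stable across days. Ties are
#' broken by earliest first occurrence, then lexicographically by id.
#'
#' @param events Single-participant event tibble with a `timestamp` column.
#' @param entity_col Name of the entity id column (`"contact_id"` or
#'   `"app_id"`).
#' @param k Number of slots (5).
#' @return Character vector of at most `k` entity ids, most frequent first.
#' @export
rank_top5 <- function(events, entity_col, k = 5) {
  if (!nrow(events)) return(character(0))
  ranked <- tibble::tibble(id = events[[entity_col]],
                           timestamp = events$timestamp) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(n = dplyr::n(), first_seen = min(.data$timestamp),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$first_seen, .data$id)
  utils::head(ranked$id, k)
}

#' Windowed normalized interaction histogram for one day
#'
#' For each of the five ranking slots, sums the event weight (count, or a
#' weight column such as call duration) over the trailing window ending on
#' day `day`, then divides by the five-slot total. An all-zero window gives
#' all zeros. Slots beyond the ranking length are zero.
#'
#' @param events Single-participant events with `timestamp` and the entity
#'   column matching `ranking`.
#' @param ranking Output of [rank_top5()].
#' @param day Study day (1-based).
#' @param study_start Date of study day 1.
#' @param entity_col Entity id column name.
#' @param weight_col Optional numeric column to sum instead of counting
#'   events.
#' @param window Window length in days; the window is `max(1, day - window
#'   + 1) .. day`.
#' @return Numeric vector of length 5.
#' @export
window_histogram <- function(events, ranking, day, study_start,
                             entity_col, weight_col = NULL, window = 3) {
  stopifnot(day >= 1)
  ev <- add_day_index(events, study_start)
  ev <- ev[ev$day_index >= max(1, day - window + 1) & ev$day_index <= day, ]
  w <- numeric(5)
  if (length(ranking)) {
    for (s in seq_along(ranking)) {
      rows <- ev[[entity_col]] == ranking[s]
      w[s] <- if (is.null(weight_col)) sum(rows) else sum(ev[[weight_col]][rows])
    }
  }
  tot <- sum(w)
  if (tot > 0) w / tot else rep(0, 5)
}

z_or_zero <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# split [start, end) into whole-second chunks per calendar day
split_session_days <- function(start, end, study_start, n_days) {
  secs <- numeric(n_days)
  if (end <= start) return(secs)
  day0 <- as.numeric(as.POSIXct(paste0(format(as.Date(study_start)),
                                       " 00:00:00"), tz = "UTC"))
  s <- as.numeric(start) - day0
  e <- as.numeric(end) - day0
  d1 <- floor(s / 86400)
  d2 <- floor((e - 1e-9) / 86400)
  for (d in d1:d2) {
    lo <- max(s, d * 86400)
    hi <- min(e, (d + 1) * 86400)
    di <- d + 1
    if (di >= 1 && di <= n_days) secs[di] <- secs[di] + (hi - lo)
  }
  secs
}

#' Daily screen-use features
#'
#' Computes, per study day, (1) the number of screen-on events and (2) the
#' total screen-on time from matched on/off event pairs, then z-scores both
#' within the participant across all study days (sample SD; a constant
#' series maps to zeros). Sessions spanning midnight are split at the
#' boundary; a trailing unmatched "on" is closed at the following midnight;
#' a leading unmatched "off" is dropped; a repeated "on" extends the open
#' session.
#'
#' @param screen Single-participant screen events: `timestamp`, `state`
#'   ("on"/"off"), time-ordered.
#' @param n_days Study length.
#' @param study_start Date of study day 1.
#' @return Tibble: `day_index`, `screen_count`, `screen_seconds`,
#'   `screen_freq_z`, `screen_dur_z` (one row per study day).
#' @export
screen_features <- function(screen, n_days, study_start) {
  screen <- screen[order(screen$timestamp), ]
  counts <- numeric(n_days)
  secs <- numeric(n_days)
  open <- NULL
  close_at <- function(open, end) split_session_days(open, end, study_start, n_days)
  for (i in seq_len(nrow(screen))) {
    ts <- screen$timestamp[i]
    if (screen$state[i] == "on") {
      d <- day_of(ts, study_start)
      if (d >= 1 && d <= n_days) counts[d] <- counts[d] + 1
      if (is.null(open)) open <- ts
    } else if (!is.null(open)) {
      secs <- secs + close_at(open, ts)
      open <- NULL
    }
  }
  if (!is.null(open)) {
    midnight <- as.POSIXct(paste0(format(as.Date(open, tz = "UTC") + 1),
                                  " 00:00:00"), tz = "UTC")
    secs <- secs + close_at(open, midnight)
  }
  tibble::tibble(day_index = seq_len(n_days),
                 screen_count = counts,
                 screen_seconds = secs,
                 screen_freq_z = z_or_zero(counts),
                 screen_dur_z = z_or_zero(secs))
}

#' Daily high-activity fraction
#'
#' Aggregates hourly accelerometer summaries (fraction of sampled time with
#' high movement) to a day value: the sample-count-weighted mean of that
#' day's hourly fractions. Days with no summaries score 0.
#'
#' @param activity Single-participant tibble: `hour_start` (POSIXct),
#'   `fraction_high` in `[0, 1]`, `n_samples`.
#' @inheritParams screen_features
#' @return Tibble: `day_index`, `activity_high_pct`.
#' @export
activity_feature <- function(activity, n_days, study_start) {
  if (nrow(activity) &&
      any(activity$fraction_high < 0 | activity$fraction_high > 1))
    rlang::abort("fraction_high outside [0, 1]",
                 class = "moodstep_validation_error")
  act <- add_day_index(activity, study_start, "hour_start") |>
    dplyr::filter(.data$day_index >= 1, .data$day_index <= n_days) |>
    dplyr::group_by(.data$day_index) |>
    dplyr::summarise(activity_high_pct =
                       stats::weighted.mean(.data$fraction_high, .data$n_samples),
                     .groups = "drop")
  tibble::tibble(day_index = seq_len(n_days)) |>
    dplyr::left_join(act, by = "day_index") |>
    dplyr::mutate(activity_high_pct = dplyr::coalesce(.data$activity_high_pct, 0))
}

#' Daily normalized photo count
#'
#' Photos taken per day divided by the participant's maximum daily count
#' (so values lie in `[0, 1]`); a participant with no photos scores all
#' zeros.
#'
#' @param camera Single-participant camera events: `timestamp`.
#' @inheritParams screen_features
#' @return Tibble: `day_index`, `images_norm`.
#' @export
image_feature <- function(camera, n_days, study_start) {
  counts <- numeric(n_days)
  if (nrow(camera)) {
    d <- day_of(camera$timestamp, study_start)
    d <- d[d >= 1 & d <= n_days]
    tb <- table(d)
    counts[as.integer(names(tb))] <- as.numeric(tb)
  }
  mx <- max(counts)
  tibble::tibble(day_index = seq_len(n_days),
                 images_norm = if (mx > 0) counts / mx else counts)
}

#' Daily app-usage features (32 variables)
#'
#' Top-5 app frequency and duration histograms (via the same windowed
#' sum-to-one normalization as the contact histograms) plus 11-category
#' frequency and duration histograms. Apps missing from the category lookup
#' count as `"unknown"`.
#'
#' @param apps Single-participant app events: `timestamp`, `app_id`,
#'   `duration_s`.
#' @param lookup Tibble `app_id`, `category` (values from
#'   [app_category_levels()]).
#' @inheritParams screen_features
#' @param window Trailing window length in days.
#' @return Tibble: `day_index` plus the 32 `app_*` schema columns.
#' @export
app_features <- function(apps, lookup, n_days, study_start, window = 3) {
  ranking <- rank_top5(apps, "app_id")
  ev <- add_day_index(apps, study_start)
  cats <- app_category_levels()
  cat_of <- lookup$category[match(ev$app_id, lookup$app_id)]
  cat_of[is.na(cat_of) | !(cat_of %in% cats)] <- "unknown"
  slots5 <- c(ranking, rep("<none>", 5 - length(ranking)))
  ones <- rep(1, nrow(ev))
  M <- cbind(
    hist_block(ev$day_index, ev$app_id, ones, slots5, n_days, window,
               "app_top5_freq_"),
    hist_block(ev$day_index, ev$app_id, ev$duration_s, slots5, n_days, window,
               "app_top5_dur_"),
    hist_block(ev$day_index, cat_of, ones, cats, n_days, window, "app_cat_freq_"),
    hist_block(ev$day_index, cat_of, ev$duration_s, cats, n_days, window,
               "app_cat_dur_")
  )
  colnames(M) <- c(paste0("app_top5_freq_", 1:5), paste0("app_top5_dur_", 1:5),
                   paste0("app_cat_freq_", cat_slug(cats)),
                   paste0("app_cat_dur_", cat_slug(cats)))
  dplyr::bind_cols(tibble::tibble(day_index = seq_len(n_days)),
                   tibble::as_tibble(M))
}

calls_sms_features <- function(calls, sms, n_days, study_start, window) {
  rk_call <- rank_top5(calls, "contact_id")
  rk_sms <- rank_top5(sms, "contact_id")
  cev <- add_day_index(calls, study_start)
  sev <- add_day_index(sms, study_start)
  s5 <- function(r) c(r, rep("<none>", 5 - length(r)))
  M <- cbind(
    hist_block(cev$day_index, cev$contact_id, rep(1, nrow(cev)), s5(rk_call),
               n_days, window, "call_top5_freq_"),
    hist_block(cev$day_index, cev$contact_id, cev$duration_s, s5(rk_call),
               n_days, window, "call_top5_dur_"),
    hist_block(sev$day_index, sev$contact_id, rep(1, nrow(sev)), s5(rk_sms),
               n_days, window, "sms_top5_freq_")
  )
  colnames(M) <- c(paste0("call_top5_freq_", 1:5), paste0("call_top5_dur_", 1:5),
                   paste0("sms_top5_freq_", 1:5))
  dplyr::bind_cols(tibble::tibble(day_index = seq_len(n_days)),
                   tibble::as_tibble(M))
}

#' Mood-history lag features
#'
#' Lag-1 and lag-2 values of the standardized target being predicted, per
#' participant-day. A lag day without a target leaves the lag `NA`, making
#' the row unusable for modeling (days 1 and 2 are always incomplete).
#'
#' @param targets Standardized daily targets ([standardize_targets()]).
#' @param measure `"mood"`, `"valence"` or `"arousal"`.
#' @return Tibble: `participant_id`, `day_index`, `mood_lag1`, `mood_lag2`.
#' @export
mood_lags <- function(targets, measure = c("mood", "valence", "arousal")) {
  measure <- match.arg(measure)
  zcol <- paste0("z_", measure)
  lag_tbl <- targets |>
    dplyr::select(dplyr::all_of(c("participant_id", "day_index", zcol)))
  grid <- targets |>
    dplyr::distinct(.data$participant_id) |>
    dplyr::cross_join(tibble::tibble(day_index = seq_len(max(targets$day_index))))
  grid |>
    dplyr::left_join(lag_tbl |> dplyr::mutate(day_index = .data$day_index + 1L) |>
                       dplyr::rename(mood_lag1 = dplyr::all_of(zcol)),
                     by = c("participant_id", "day_index")) |>
    dplyr::left_join(lag_tbl |> dplyr::mutate(day_index = .data$day_index + 2L) |>
                       dplyr::rename(mood_lag2 = dplyr::all_of(zcol)),
                     by = c("participant_id", "day_index"))
}

# 51 behaviour columns (everything except the mood-history lags) for one
# participant, one row per study day
participant_behaviour_features <- function(streams, n_days, study_start,
                                           window = 3, lookup = NULL) {
  if (is.null(lookup))
    lookup <- tibble::tibble(app_id = character(0), category = character(0))
  calls_sms_features(streams$calls, streams$sms, n_days, study_start, window) |>
    dplyr::left_join(activity_feature(streams$activity, n_days, study_start),
                     by = "day_index") |>
    dplyr::left_join(screen_features(streams$screen, n_days, study_start) |>
                       dplyr::select(-"screen_count", -"screen_seconds"),
                     by = "day_index") |>
    dplyr::left_join(app_features(streams$apps, lookup, n_days, study_start,
                                  window),
                     by = "day_index") |>
    dplyr::left_join(image_feature(streams$camera, n_days, study_start),
                     by = "day_index")
}

one_participant_streams <- function(study, pid) {
  lapply(study[c("calls", "sms", "screen", "apps", "camera", "activity")],
         function(s) s[s$participant_id == pid, , drop = FALSE])
}

#' Build the daily predictor table
#'
#' Assembles, for every participant-day of the study, the 53 predictor
#' variables of [feature_schema()] in schema order, the standardized target
#' for `measure`, and a `modelable` flag (TRUE when the day has a target
#' and both mood-history lags). Days with no events in a channel score
#' zeros on that channel's variables; only missing targets or lags make a
#' row non-modelable.
#'
#' @param study A `mood_study` bundle ([simulate_study()] /
#'   [read_streams()]).
#' @param targets Standardized daily targets.
#' @param measure Target measure; its z-score becomes both the `target`
#'   column and the lag features.
#' @param window Histogram window length in days (window ends on the
#'   predicted day).
#' @return Tibble: `participant_id`, `day_index`, the 53 schema columns,
#'   `target`, `modelable`.
#' @export
build_feature_table <- function(study, targets,
                                measure = c("mood", "valence", "arousal"),
                                window = 3) {
  measure <- match.arg(measure)
  n_days <- study$config$n_days
  start <- study$config$study_start
  zcol <- paste0("z_", measure)
  pids <- sort(unique(targets$participant_id))
  lags <- mood_lags(targets, measure)
  beh <- purrr::map(pids, function(pid) {
    participant_behaviour_features(one_participant_streams(study, pid),
                                   n_days, start, window,
                                   study$app_categories) |>
      dplyr::mutate(participant_id = pid, .before = 1)
  }) |>
    purrr::list_rbind()
  out <- beh |>
    dplyr::left_join(lags, by = c("participant_id", "day_index")) |>
    dplyr::left_join(targets |>
                       dplyr::select(dplyr::all_of(c("participant_id",
                                                     "day_index", zcol))) |>
                       dplyr::rename(target = dplyr::all_of(zcol)),
                     by = c("participant_id", "day_index")) |>
    dplyr::mutate(modelable = !is.na(.data$target) & !is.na(.data$mood_lag1) &
                    !is.na(.data$mood_lag2))
  cols <- c("participant_id", "day_index", feature_variables(),
            "target", "modelable")
  if (!all(cols %in% names(out)))
    rlang::abort("feature schema mismatch while assembling the table",
                 class = "moodstep_schema_error")
  out <- out[, cols]
  attr(out, "measure") <- measure
  out
}
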
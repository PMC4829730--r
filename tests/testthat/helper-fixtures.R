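# Shared fixtures and independent oracles used across the suite. Oracles are
# written as plainly as possible (explicit refit loops, naive re-scans) so
# they stay independent of the package's optimized code paths.

study_day1 <- as.Date("2016-01-04")

ts_at <- function(day, hour = 12, min = 0, sec = 0) {
  as.POSIXct(paste0(format(study_day1 + (day - 1)),
                    sprintf(" %02d:%02d:%02d", hour, min, sec)), tz = "UTC")
}

# minimal mood-rating stream: one participant, one rating triple per entry
make_ratings <- function(days, mood, valence = 0L, arousal = 0L,
                         pid = "p001", hour = 12) {
  tibble::tibble(participant_id = pid,
                 timestamp = ts_at(days, hour),
                 mood = as.integer(mood),
                 valence = as.integer(rep_len(valence, length(days))),
                 arousal = as.integer(rep_len(arousal, length(days))))
}

# a synthetic feature table built directly (bypassing the event pipeline):
# p predictors drawn iid N(0,1) named after the first schema variables, plus
# lag columns consistent with the target series
make_toy_features <- function(n_days, target, p = 5, pid = "p001",
                              seed = 42) {
  set.seed(seed)
  vars <- setdiff(feature_variables(), c("mood_lag1", "mood_lag2"))[seq_len(p)]
  X <- matrix(rnorm(n_days * p), n_days, p, dimnames = list(NULL, vars))
  tb <- tibble::as_tibble(X)
  tb$participant_id <- pid
  tb$day_index <- seq_len(n_days)
  tb$mood_lag1 <- dplyr::lag(target, 1)
  tb$mood_lag2 <- dplyr::lag(target, 2)
  tb$target <- target
  tb$modelable <- !is.na(tb$mood_lag1) & !is.na(tb$mood_lag2) & !is.na(target)
  attr(tb, "measure") <- "mood"
  tb
}

# explicit leave-one-out CV MSE by refitting lm() n times
refit_loocv_mse <- function(data, target, predictors) {
  n <- nrow(data)
  fml <- if (length(predictors))
    stats::reformulate(predictors, response = target) else
    stats::as.formula(paste(target, "~ 1"))
  mean(vapply(seq_len(n), function(i) {
    fit <- stats::lm(fml, data = data[-i, , drop = FALSE])
    (data[[target]][i] - unname(stats::predict(fit, data[i, , drop = FALSE])))^2
  }, numeric(1)))
}

# naive re-scan histogram: re-filters the raw events by calendar date for
# every slot, without any rolling-window machinery
naive_window_hist <- function(events, ranking, day, start, entity_col,
                              weight_col = NULL, window = 3) {
  lo <- start + (max(1, day - window + 1) - 1)
  hi <- start + (day - 1)
  w <- numeric(5)
  for (s in seq_along(ranking)) {
    tot <- 0
    for (i in seq_len(nrow(events))) {
      d <- as.Date(events$timestamp[i], tz = "UTC")
      if (d >= lo && d <= hi && events[[entity_col]][i] == ranking[s])
        tot <- tot + if (is.null(weight_col)) 1 else events[[weight_col]][i]
    }
    w[s] <- tot
  }
  if (sum(w) > 0) w / sum(w) else rep(0, 5)
}

null_coupling <- function() coupling_spec(ar_coefficient = 0)

small_study_config <- function(seed = 7, n_participants = 2, n_days = 12, ...) {
  study_config(n_participants = n_participants, n_days = n_days, seed = seed,
               ...)
}
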
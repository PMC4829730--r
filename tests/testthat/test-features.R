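mk_events <- function(days, ids, durations = NULL, entity = "contact_id",
                      hour = 10) {
  tb <- tibble::tibble(participant_id = "p001",
                       timestamp = ts_at(days, hour) + seq_along(days))
  tb[[entity]] <- ids
  if (!is.null(durations)) tb$duration_s <- durations
  tb
}

test_that("top-5 ranking orders by count with first-seen then id tie-breaks", {
  ev <- mk_events(c(1, 1, 1, 2, 2, 3), c("A", "A", "A", "B", "B", "C"))
  expect_equal(rank_top5(ev, "contact_id"), c("A", "B", "C"))
  # tie on count: A first seen before B
  tie <- mk_events(c(1, 2, 1, 2, 3, 3),
                   c("A", "A", "A", "B", "B", "B"))
  expect_equal(rank_top5(tie, "contact_id")[1], "A")
  # count and first-seen tie (same second is impossible here; same day):
  # lexicographic id decides among equal counts with equal first timestamps
  same <- tibble::tibble(participant_id = "p001",
                         timestamp = rep(ts_at(1), 2),
                         contact_id = c("Z", "B"))
  expect_equal(rank_top5(same, "contact_id"), c("B", "Z"))
  expect_equal(rank_top5(ev[0, ], "contact_id"), character(0))
})

test_that("windowed histograms normalize to one and handle empty windows", {
  ev <- mk_events(c(3, 3, 2, 1), c("A", "B", "A", "B"))
  rk <- rank_top5(ev, "contact_id")
  h <- window_histogram(ev, rk, day = 3, study_day1, "contact_id")
  expect_equal(sum(h), 1)
  expect_equal(length(h), 5)
  # day 6: window 4..6 holds no events -> all zeros
  expect_equal(window_histogram(ev, rk, 6, study_day1, "contact_id"),
               rep(0, 5))
  # weighted variant: durations
  evd <- mk_events(c(1, 1), c("A", "B"), durations = c(30, 10))
  expect_equal(window_histogram(evd, c("A", "B"), 1, study_day1,
                                "contact_id", "duration_s"),
               c(0.75, 0.25, 0, 0, 0))
  expect_equal(window_histogram(ev, character(0), 1, study_day1, "contact_id"),
               rep(0, 5))
})

test_that("pipeline histograms equal a naive event re-scan on random days", {
  cfg <- small_study_config(seed = 31, n_participants = 2, n_days = 12)
  study <- simulate_study(cfg)
  set.seed(5)
  for (pid in c("p001", "p002")) {
    calls <- study$calls[study$calls$participant_id == pid, ]
    rk <- rank_top5(calls, "contact_id")
    for (day in sample(1:12, 13, replace = TRUE)) {
      expect_equal(
        window_histogram(calls, rk, day, cfg$study_start, "contact_id"),
        naive_window_hist(calls, rk, day, cfg$study_start, "contact_id"),
        tolerance = 1e-12)
      expect_equal(
        window_histogram(calls, rk, day, cfg$study_start, "contact_id",
                         "duration_s"),
        naive_window_hist(calls, rk, day, cfg$study_start, "contact_id",
                          "duration_s"),
        tolerance = 1e-12)
    }
  }
})

test_that("screen features count on-events and split sessions at midnight", {
  scr <- tibble::tibble(
    participant_id = "p001",
    timestamp = c(ts_at(1, 10, 0), ts_at(1, 10, 5),
                  ts_at(1, 12, 0), ts_at(1, 12, 10)),
    state = c("on", "off", "on", "off"))
  f <- screen_features(scr, n_days = 3, study_day1)
  expect_equal(f$screen_count[1], 2)
  expect_equal(f$screen_seconds[1], 900)
  # session crossing midnight: 23:50 on day 1 -> 00:10 on day 2
  cross <- tibble::tibble(
    participant_id = "p001",
    timestamp = c(ts_at(1, 23, 50), ts_at(2, 0, 10)),
    state = c("on", "off"))
  g <- screen_features(cross, n_days = 3, study_day1)
  expect_equal(g$screen_seconds[1:2], c(600, 600))
  expect_equal(g$screen_count, c(1, 0, 0))
  # daily counts (1,2,3) standardize to (-1,0,1); leading off dropped;
  # trailing on closes at midnight
  mixed <- tibble::tibble(
    participant_id = "p001",
    timestamp = c(ts_at(1, 8), ts_at(1, 9, 0), ts_at(1, 9, 1),
                  ts_at(2, 9), ts_at(2, 9, 1), ts_at(2, 10), ts_at(2, 10, 1),
                  ts_at(3, 9), ts_at(3, 9, 1), ts_at(3, 10), ts_at(3, 10, 1),
                  ts_at(3, 23, 59)),
    state = c("off", "on", "off", "on", "off", "on", "off",
              "on", "off", "on", "off", "on"))
  h <- screen_features(mixed, n_days = 3, study_day1)
  expect_equal(h$screen_count, c(1, 2, 3))
  expect_equal(h$screen_freq_z, c(-1, 0, 1))
  expect_equal(h$screen_seconds[3], 60 + 60 + 60)  # trailing on: 1 min to midnight
})

test_that("activity aggregates hourly fractions by sample-count weights", {
  act <- tibble::tibble(participant_id = "p001",
                        hour_start = c(ts_at(1, 10), ts_at(1, 11), ts_at(2, 9)),
                        fraction_high = c(0.2, 0.4, 0),
                        n_samples = c(60, 60, 60))
  f <- activity_feature(act, 3, study_day1)
  expect_equal(f$activity_high_pct, c(0.3, 0, 0))
  weighted <- tibble::tibble(participant_id = "p001",
                             hour_start = c(ts_at(1, 10), ts_at(1, 11)),
                             fraction_high = c(0.2, 0.6),
                             n_samples = c(300, 100))
  expect_equal(activity_feature(weighted, 1, study_day1)$activity_high_pct, 0.3)
  bad <- dplyr::mutate(act, fraction_high = c(0.2, 1.4, 0))
  expect_error(activity_feature(bad, 3, study_day1),
               class = "moodstep_validation_error")
})

test_that("image counts are max-normalized per participant", {
  cam <- tibble::tibble(participant_id = "p001",
                        timestamp = ts_at(c(2, 2, 2, 2, 2, 3, 3, 3, 3, 3,
                                            3, 3, 3, 3, 3)))
  f <- image_feature(cam, 3, study_day1)
  expect_equal(f$images_norm, c(0, 0.5, 1))
  empty <- image_feature(cam[0, ], 3, study_day1)
  expect_equal(empty$images_norm, c(0, 0, 0))
  const <- image_feature(tibble::tibble(participant_id = "p001",
                                        timestamp = ts_at(1:3)), 3, study_day1)
  expect_equal(const$images_norm, c(1, 1, 1))
})

test_that("app features emit 32 columns with unit-sum category histograms", {
  apps <- mk_events(c(1, 1, 2), c("a1", "a2", "a1"), durations = c(60, 30, 10),
                    entity = "app_id")
  lookup <- tibble::tibble(app_id = c("a1", "a2"),
                           category = c("games", "social"))
  f <- app_features(apps, lookup, 3, study_day1)
  expect_equal(ncol(f) - 1, 32)
  catf <- as.matrix(f[, grep("^app_cat_freq_", names(f))])
  expect_equal(unname(rowSums(catf)), c(1, 1, 1))
  # day 2 window covers days 1-2: games seen twice, social once
  expect_equal(f$app_cat_freq_games[2], 2 / 3)
  # unmapped app falls into "unknown"
  f2 <- app_features(apps, lookup[0, ], 3, study_day1)
  expect_equal(f2$app_cat_freq_unknown, c(1, 1, 1))
  # all usage in one category -> that category 1, others 0
  one <- app_features(mk_events(1, "a1", durations = 5, entity = "app_id"),
                      lookup, 1, study_day1)
  expect_equal(one$app_cat_dur_games, 1)
  expect_equal(sum(as.matrix(one[, grep("^app_cat_dur_", names(one))])), 1)
})

test_that("mood lags shift the standardized series and flag early days", {
  targets <- tibble::tibble(participant_id = "p001", day_index = 1:3,
                            z_mood = c(10, 20, 30))
  lg <- mood_lags(targets, "mood")
  expect_equal(lg$mood_lag1[lg$day_index == 3], 20)
  expect_equal(lg$mood_lag2[lg$day_index == 3], 10)
  expect_true(all(is.na(lg$mood_lag2[lg$day_index <= 2])))
  expect_true(is.na(lg$mood_lag1[lg$day_index == 1]))
})

test_that("the assembled table has 53 predictors with histogram bounds", {
  cfg <- small_study_config(seed = 13, n_participants = 2, n_days = 12,
                            missing_day_prob = 0.1)
  study <- simulate_study(cfg)
  targets <- standardize_targets(aggregate_daily(study$mood, cfg$study_start))
  ft <- build_feature_table(study, targets, "mood")
  sc <- feature_schema()
  expect_equal(setdiff(names(ft), c("participant_id", "day_index", "target",
                                    "modelable")), sc$variable)
  expect_equal(sum(sc$block == "calls_sms"), 15)
  expect_equal(sum(sc$block == "apps"), 32)
  hist_vars <- sc$variable[grepl("top5|app_cat", sc$variable)]
  H <- as.matrix(ft[, hist_vars])
  expect_true(all(H >= 0 & H <= 1))
  expect_true(all(ft$activity_high_pct >= 0 & ft$activity_high_pct <= 1))
  expect_true(all(ft$images_norm >= 0 & ft$images_norm <= 1))
  # each 5-slot / 11-bin group sums to 1 or is all zero
  for (grp in c("call_top5_freq_", "call_top5_dur_", "sms_top5_freq_",
                "app_top5_freq_", "app_top5_dur_", "app_cat_freq_",
                "app_cat_dur_")) {
    s <- rowSums(as.matrix(ft[, grep(paste0("^", grp), names(ft))]))
    expect_true(all(abs(s - 1) < 1e-9 | s == 0))
  }
  # z-scored screen features: per-participant mean 0, sample SD 1
  for (pid in unique(ft$participant_id)) {
    v <- ft$screen_freq_z[ft$participant_id == pid]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sd(v) - 1), 1e-9)
  }
  # rows missing lags or targets are flagged non-modelable
  expect_true(all(!ft$modelable[ft$day_index <= 2]))
  expect_true(all(stats::complete.cases(
    ft[ft$modelable, c(sc$variable, "target")])))
})
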
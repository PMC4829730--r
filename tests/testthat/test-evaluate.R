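test_that("mean-model LOOCV equals the leave-one-out-mean closed form", {
  set.seed(9)
  y <- rnorm(9)
  ft <- make_toy_features(9, y, p = 3)
  pr <- loocv_evaluate(ft, "mean")
  held <- ft$target[ft$modelable]
  n <- length(held)
  closed <- (sum(held) - held) / (n - 1)  # mean of the other rows
  expect_equal(pr$predicted_z, closed, tolerance = 1e-12)
  expect_equal(pr$abs_error, abs(held - closed), tolerance = 1e-12)
})

test_that("the error margin is inclusive at exactly 0.5", {
  y <- c(NA, NA, 1, 1, 1, 1.5)  # LOO residual for the last row is exactly 0.5
  ft <- make_toy_features(6, c(0, 0, y[3:6]), p = 2)
  pr <- loocv_evaluate(ft, "mean")
  expect_equal(max(pr$abs_error), 0.5)
  expect_true(all(pr$correct))
  perf <- participant_performance(pr)
  expect_equal(perf$pct_correct, 100)
})

test_that("participants with too few modelable days are skipped with a warning", {
  ft <- make_toy_features(5, c(1, 2, 1.5, 2.5, NA), p = 2)
  expect_warning(pr <- loocv_evaluate(ft, "mean"), "skipped")
  expect_equal(nrow(pr), 0)
})

test_that("stepCV held-out predictions equal a from-scratch per-fold refit", {
  set.seed(71)
  y <- rnorm(18)
  ft <- make_toy_features(18, y, p = 4, seed = 72)
  pr <- loocv_evaluate(ft, "stepCV")
  rows <- ft[ft$modelable, ]
  vars <- setdiff(feature_variables(), c("mood_lag1", "mood_lag2"))[1:4]
  cand <- c(vars, "mood_lag1", "mood_lag2")
  for (i in seq_len(nrow(rows))) {
    # independent re-selection: greedy PRESS minimization via refit_loocv_mse
    train <- rows[-i, ]
    sel <- character(0)
    cur <- refit_loocv_mse(train, "target", sel)
    repeat {
      if (length(sel) >= cap_variables(nrow(train))) break
      scores <- vapply(setdiff(cand, sel), function(v)
        refit_loocv_mse(train, "target", c(sel, v)), numeric(1))
      best <- names(scores)[which.min(scores)]
      if (min(scores) >= cur) break
      # replicate the schema-order tie-break: first candidate within 1e-12
      best <- setdiff(cand, sel)[which(scores < min(scores) + 1e-12)[1]]
      sel <- c(sel, best)
      cur <- min(scores)
    }
    fml <- if (length(sel)) stats::reformulate(sel, "target")
           else target ~ 1
    ref <- stats::predict(stats::lm(fml, train), rows[i, ])
    expect_equal(pr$predicted_z[i], unname(ref), tolerance = 1e-8)
  }
})

test_that("prediction order does not affect per-participant performance", {
  set.seed(15)
  y <- rnorm(10)
  ft <- make_toy_features(10, y, p = 3)
  shuf <- ft[sample(nrow(ft)), ]
  attr(shuf, "measure") <- "mood"
  p1 <- participant_performance(loocv_evaluate(ft, "history"))
  p2 <- participant_performance(loocv_evaluate(shuf, "history"))
  expect_equal(p1$cv_mse, p2$cv_mse, tolerance = 1e-12)
  expect_equal(p1$pct_correct, p2$pct_correct)
})

test_that("the signed-rank test matches hand-computed ranks and wilcox.test", {
  # eight pairs, signed differences with hand-ranked |d|:
  # |d|: 0.1<0.3<0.6<0.9<1.2<1.5<2.1<2.4, positives hold ranks 2,4,5,6,7
  a <- c(10.3, 9.4, 11.2, 7.6, 10.9, 11.5, 9.9, 12.1)
  b <- c(10.0, 10.0, 10.0, 10.0, 10.0, 10.0, 10.0, 10.0)
  w <- moodstep:::wilcoxon_signed_rank(a - b)
  expect_equal(w$statistic, 2 + 4 + 5 + 6 + 7)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(w$statistic, unname(ref$statistic))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)

  # identical vectors degenerate to p = 1
  perf <- tibble::tibble(participant_id = rep(sprintf("p%02d", 1:8), 2),
                         measure = "mood",
                         family = rep(c("stepCV", "mean"), each = 8),
                         cv_mse = rep(a, 2),
                         pct_correct = 50, n_predictions = 10)
  cmp <- compare_families(perf, "stepCV", "mean", "cv_mse")
  expect_true(cmp$degenerate)
  expect_equal(cmp$p_value, 1)

  # uniformly shifted pairs at n = 27: overwhelming one-sided evidence
  set.seed(2)
  base <- rnorm(27)
  perf2 <- tibble::tibble(participant_id = rep(sprintf("p%02d", 1:27), 2),
                          measure = "mood",
                          family = rep(c("stepCV", "mean"), each = 27),
                          cv_mse = c(base + 0.4, base),
                          pct_correct = 50, n_predictions = 10)
  cmp2 <- compare_families(perf2, "stepCV", "mean", "cv_mse")
  expect_lt(cmp2$p_value, 0.001)
  expect_equal(cmp2$n_pairs, 27L)
})

test_that("incremental evaluation trains strictly on earlier days", {
  set.seed(19)
  y <- rnorm(14)
  ft <- make_toy_features(14, y, p = 3)
  inc <- incremental_evaluate(ft, families = c("mean", "history"),
                              start_day = 8)
  expect_true(all(inc$predictions$day_index >= 8))
  # mean-model prediction for day d must be the mean of modelable days < d
  rows <- ft[ft$modelable, ]
  for (i in which(inc$predictions$family == "mean")) {
    d <- inc$predictions$day_index[i]
    expect_equal(inc$predictions$predicted_z[i],
                 mean(rows$target[rows$day_index < d]), tolerance = 1e-12)
  }
  # trend regression equals an independent normal-equations fit
  ref <- inc$daily[inc$daily$family == "mean", ]
  fam <- inc$daily[inc$daily$family == "history", ]
  joined <- merge(fam, ref, by = "day_index")
  A <- cbind(1, joined$day_index)
  diff <- joined$mse.x - joined$mse.y
  beta <- solve(t(A) %*% A, t(A) %*% diff)
  tr <- inc$trend[inc$trend$metric == "mse", ]
  expect_equal(tr$intercept_estimate, beta[1], tolerance = 1e-9)
  expect_equal(tr$slope_estimate, beta[2], tolerance = 1e-9)
  resid <- diff - A %*% beta
  s2 <- sum(resid^2) / (nrow(A) - 2)
  se <- sqrt(diag(s2 * solve(t(A) %*% A)))
  expect_equal(c(tr$intercept_se, tr$slope_se), unname(se), tolerance = 1e-9)
  expect_true(all(c(tr$intercept_se, tr$slope_se) > 0))
})

test_that("a family compared against itself shows a zero trend", {
  daily <- tibble::tibble(family = rep(c("mean", "self"), each = 10),
                          day_index = rep(8:17, 2),
                          mse = rep(runif(10), 2),
                          pct_correct = rep(runif(10, 0, 100), 2),
                          n = 5)
  tr <- moodstep:::incremental_trend(daily, "mood")
  expect_equal(tr$intercept_estimate, c(0, 0), tolerance = 1e-12)
  expect_equal(tr$slope_estimate, c(0, 0), tolerance = 1e-12)
})

test_that("the report aggregates with CIs centred on the mean", {
  set.seed(4)
  perf <- tibble::tibble(participant_id = sprintf("p%02d", 1:10),
                         measure = "mood", family = "mean",
                         cv_mse = runif(10), pct_correct = runif(10, 0, 100),
                         n_predictions = 30)
  rep1 <- summarize_report(perf)
  tab <- rep1$performance_table
  expect_equal(tab$mean_cv_mse, mean(perf$cv_mse))
  expect_equal((tab$cv_mse_lo + tab$cv_mse_hi) / 2, tab$mean_cv_mse,
               tolerance = 1e-12)
  # a single participant cannot carry a CI
  single <- summarize_report(perf[1, ])$performance_table
  expect_true(is.na(single$cv_mse_lo))
})

test_that("personalized selection wins when behaviour truly drives mood", {
  cfg <- study_config(
    n_participants = 27, n_days = 42, seed = 271,
    coupling = coupling_spec(effect_vector = c(screen_freq_z = 1,
                                               activity_high_pct = 1),
                             noise_sd = 0.2))
  study <- simulate_study(cfg)
  targets <- standardize_targets(aggregate_daily(study$mood, cfg$study_start))
  ft <- build_feature_table(study, targets, "mood")
  adher <- prune_participants(targets, ft)
  keep <- adher$participant_id[adher$included]
  ft <- ft[ft$participant_id %in% keep, ]
  attr(ft, "measure") <- "mood"
  perf <- participant_performance(
    dplyr::bind_rows(loocv_evaluate(ft, "mean"), loocv_evaluate(ft, "stepCV")))
  wide <- tidyr::pivot_wider(
    dplyr::select(perf, participant_id, family, cv_mse),
    names_from = family, values_from = cv_mse)
  expect_gte(mean(wide$stepCV < wide$mean), 0.70)
})
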
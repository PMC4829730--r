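# Synthetic study generator: per-participant smartphone event streams (calls,
# SMS, screen sessions, app launches, camera, hourly accelerometer activity
# summaries) and a mood diary driven by a latent AR(1) mood process that can
# be linearly coupled to the day's standardized behaviour features.
#
# Determinism: one master seed; participant i draws everything from the child
# seed master + i, so a single participant regenerates identically whatever
# the cohort size. The caller's RNG state is saved and restored.

zipf_weights <- function(n, exponent = 1) {
  w <- 1 / seq_len(n)^exponent
  w / sum(w)
}

rand_times <- function(date, n, lo = 8, hi = 23) {
  # upper bound shaved so rounding can never spill past the day boundary
  as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC") +
    round(stats::runif(n, lo * 3600, hi * 3600 - 1))
}

# latent-to-rating scale map: raw-scale location/spread of each diary measure
measure_scales <- function() {
  list(mood    = list(mu = 7.0,  sd = 0.95, lo = 1,  hi = 10),
       valence = list(mu = 0.7,  sd = 0.63, lo = -2, hi = 2),
       arousal = list(mu = -0.1, sd = 1.00, lo = -2, hi = 2))
}

default_app_universe <- function(n_apps, seed) {
  cats <- app_category_levels()
  # plausible mix for student phone use: messaging/social/games dominate
  wts <- c(`built-in` = 3, communication = 5, entertainment = 3, finance = 1,
           games = 4, office = 1, social = 5, travel = 1, utilities = 2,
           other = 1, unknown = 1)
  withr_seed(seed, {
    tibble::tibble(app_id = sprintf("a%03d", seq_len(n_apps)),
                   category = sample(cats, n_apps, replace = TRUE,
                                     prob = wts[cats]))
  })
}

# evaluate `expr` under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

simulate_participant_events <- function(cfg, pid, missing_day) {
  n_days <- cfg$n_days
  days <- seq_len(n_days)[!missing_day]
  dates <- cfg$study_start + (days - 1)
  # participant-level usage intensity (lognormal heterogeneity) and a
  # personal popularity order over the shared contact/app universes
  rate_mult <- stats::rlnorm(5, 0, 0.3)
  contact_order <- sample(sprintf("c%03d", seq_len(cfg$n_contacts)))
  app_order <- sample(sprintf("a%03d", seq_len(cfg$n_apps)))
  pw_contact <- zipf_weights(cfg$n_contacts)
  pw_app <- zipf_weights(cfg$n_apps)

  per_day <- function(lam) stats::rpois(length(days), lam)

  n_call <- per_day(5 * rate_mult[1])
  calls <- tibble::tibble(
    participant_id = pid,
    timestamp = rand_times(rep(dates, n_call), sum(n_call)),
    direction = sample(c("incoming", "outgoing"), sum(n_call), replace = TRUE),
    contact_id = sample(contact_order, sum(n_call), replace = TRUE,
                        prob = pw_contact),
    duration_s = round(stats::rlnorm(sum(n_call), log(120), 1)))

  n_sms <- per_day(2 * rate_mult[2])
  sms <- tibble::tibble(
    participant_id = pid,
    timestamp = rand_times(rep(dates, n_sms), sum(n_sms)),
    contact_id = sample(contact_order, sum(n_sms), replace = TRUE,
                        prob = pw_contact))

  # screen sessions: starts within the day, log-normal lengths, clipped so
  # on/off events alternate and never spill onto a missing (or post-study) day
  n_scr <- per_day(60 * rate_mult[3])
  day_rep <- rep(days, n_scr)
  start <- as.numeric(rand_times(rep(dates, n_scr), sum(n_scr), 0, 24)) -
    as.numeric(as.POSIXct(paste0(format(cfg$study_start), " 00:00:00"),
                          tz = "UTC")) # seconds since study start
  len <- round(stats::rlnorm(sum(n_scr), log(60), 1))
  o <- order(start)
  start <- start[o]; len <- len[o]; day_rep <- day_rep[o]
  end <- start + pmax(1, len)
  if (length(start) > 1)
    end[-length(end)] <- pmin(end[-length(end)], start[-1] - 1)
  # close at midnight when the next calendar day is unobserved
  next_missing <- c(missing_day, TRUE)[day_rep + 1L]
  day_end <- day_rep * 86400
  end <- ifelse(next_missing, pmin(end, day_end - 1), end)
  keep <- end > start
  base <- as.POSIXct(paste0(format(cfg$study_start), " 00:00:00"), tz = "UTC")
  screen <- tibble::tibble(
    participant_id = pid,
    timestamp = base + as.vector(rbind(start[keep], end[keep])),
    state = rep(c("on", "off"), sum(keep)))

  n_app <- per_day(100 * rate_mult[4])
  apps <- tibble::tibble(
    participant_id = pid,
    timestamp = rand_times(rep(dates, n_app), sum(n_app), 7, 24),
    app_id = sample(app_order, sum(n_app), replace = TRUE, prob = pw_app),
    duration_s = round(stats::rlnorm(sum(n_app), log(90), 1)))

  n_cam <- per_day(2 * rate_mult[5])
  camera <- tibble::tibble(
    participant_id = pid,
    timestamp = rand_times(rep(dates, n_cam), sum(n_cam)))

  hours <- as.POSIXct(paste0(format(rep(dates, each = 24)), " 00:00:00"),
                      tz = "UTC") + rep(0:23, length(days)) * 3600
  day_act <- stats::rbeta(length(days), 2, 8) # participant-day activity level
  frac <- stats::rbeta(24 * length(days),
                       shape1 = 1 + 10 * rep(day_act, each = 24), shape2 = 9)
  activity <- tibble::tibble(
    participant_id = pid,
    hour_start = hours,
    fraction_high = round(frac, 4),
    n_samples = sample(55:60, 24 * length(days), replace = TRUE))

  list(calls = calls, sms = sms, screen = screen, apps = apps,
       camera = camera, activity = activity)
}

standardize_columns <- function(M) {
  apply(M, 2, z_or_zero)
}

simulate_participant <- function(cfg, i, app_lookup) {
  pid <- sprintf("p%03d", i)
  withr_seed(cfg$seed + i, {
    missing_day <- stats::runif(cfg$n_days) < cfg$missing_day_prob
    streams <- simulate_participant_events(cfg, pid, missing_day)

    # standardized behaviour features of each day drive the latent mood
    beh <- participant_behaviour_features(streams, cfg$n_days,
                                          cfg$study_start, 3, app_lookup)
    ev <- cfg$coupling$effect_vector
    drive <- rep(0, cfg$n_days)
    if (length(ev)) {
      Fm <- standardize_columns(as.matrix(beh[, names(ev), drop = FALSE]))
      drive <- drop(Fm %*% ev)
    }
    ar <- cfg$coupling$ar_coefficient
    eps <- stats::rnorm(cfg$n_days, 0, cfg$coupling$noise_sd)
    latent <- numeric(cfg$n_days)
    latent[1] <- drive[1] + eps[1] / sqrt(1 - ar^2)
    for (d in seq_len(cfg$n_days)[-1])
      latent[d] <- ar * latent[d - 1] + drive[d] + eps[d]

    sc <- measure_scales()
    rate_days <- which(!missing_day)
    rows <- list()
    for (d in rate_days) {
      keep <- stats::runif(cfg$ratings_per_day) >= cfg$missing_rating_prob
      ts <- as.POSIXct(paste0(format(cfg$study_start + (d - 1)),
                              " 00:00:00"), tz = "UTC") +
        cfg$rating_times * 3600
      if (!any(keep)) next
      k <- sum(keep)
      meas_noise <- matrix(stats::rnorm(3 * k, 0, cfg$coupling$measurement_sd),
                           k, 3)
      rate1 <- function(j, s) {
        raw <- s$mu + s$sd * (latent[d] + meas_noise[, j])
        pmin(pmax(round(raw), s$lo), s$hi)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = pid,
        timestamp = ts[keep],
        mood = as.integer(rate1(1, sc$mood)),
        valence = as.integer(rate1(2, sc$valence)),
        arousal = as.integer(rate1(3, sc$arousal)))
    }
    mood <- if (length(rows)) purrr::list_rbind(rows) else
      tibble::tibble(participant_id = character(0),
                     timestamp = as.POSIXct(character(0), tz = "UTC"),
                     mood = integer(0), valence = integer(0),
                     arousal = integer(0))
    list(streams = streams, mood = mood,
         latent = tibble::tibble(participant_id = pid,
                                 day_index = seq_len(cfg$n_days),
                                 latent = latent,
                                 missing = missing_day))
  })
}

#' Simulate a full study
#'
#' Generates the six per-participant sensor streams and the mood diary for
#' every participant under `config`. Behaviour is independent of mood unless
#' the coupling carries a nonzero `effect_vector`, in which case the latent
#' daily mood follows an AR(1) process plus a linear function of the day's
#' standardized behaviour features; diary ratings are the latent value mapped
#' to each scale, perturbed by measurement noise, rounded and clipped.
#'
#' @param config A [study_config()].
#' @return A `mood_study` list: `config`; event tibbles `calls`, `sms`,
#'   `screen`, `apps`, `camera`, `activity`, `mood` (all participants
#'   stacked); `app_categories` lookup; and `latent` (the ground-truth daily
#'   latent mood and the missing-day flags, for parameter-recovery checks).
#' @export
#' @examples
#' study <- simulate_study(study_config(n_participants = 1, n_days = 10, seed = 7))
#' dplyr::count(study$mood, participant_id)
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  app_lookup <- default_app_universe(config$n_apps, config$seed)
  parts <- lapply(seq_len(config$n_participants),
                  function(i) simulate_participant(config, i, app_lookup))
  pick <- function(field, sub = NULL) {
    purrr::list_rbind(lapply(parts, function(p)
      if (is.null(sub)) p[[field]] else p[[field]][[sub]]))
  }
  structure(list(config = config,
                 calls = pick("streams", "calls"),
                 sms = pick("streams", "sms"),
                 screen = pick("streams", "screen"),
                 apps = pick("streams", "apps"),
                 camera = pick("streams", "camera"),
                 activity = pick("streams", "activity"),
                 mood = pick("mood"),
                 app_categories = app_lookup,
                 latent = pick("latent")),
            class = "mood_study")
}

#' @export
print.mood_study <- function(x, ...) {
  cat("<mood_study> ", x$config$n_participants, " participants x ",
      x$config$n_days, " days; ", nrow(x$mood), " mood ratings, ",
      nrow(x$apps), " app events\n", sep = "")
  invisible(x)
}
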
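# Study and coupling configuration with field-level validation. Defaults
# mirror the study design the pipeline emulates: 42 days, five mood prompts
# per day at 09/12/15/18/21h, pruning at 20 complete days.

abort_config <- function(field, msg) {
  rlang::abort(sprintf("invalid configuration: `%s` %s", field, msg),
               class = "moodstep_config_error", field = field)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort_config(field, "must be a probability in [0, 1]")
  x
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    abort_config(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

#' Latent mood coupling specification
#'
#' Ground-truth parameters of the latent daily mood process used by
#' [simulate_study()]: an AR(1) carry-over from the previous day, a linear
#' coupling onto the standardized daily behaviour features, innovation noise,
#' and measurement noise added to each individual diary rating. The coupling
#' acts on standardized features, so `effect_vector` coefficients are in
#' standardized-mood units per standardized-feature unit.
#'
#' @param effect_vector Named numeric vector; names must be predictor
#'   variables from [feature_schema()] (mood-history lags excluded -- history
#'   dependence is expressed through `ar_coefficient`). An empty vector means
#'   mood is uncoupled from behaviour.
#' @param ar_coefficient Day-to-day autoregressive coefficient, in (-1, 1).
#' @param noise_sd Standard deviation of the daily latent innovation (> 0).
#' @param measurement_sd Standard deviation of per-rating measurement noise
#'   on the standardized scale (> 0).
#' @return A list of class `coupling_spec`.
#' @export
#' @examples
#' coupling_spec(effect_vector = c(screen_freq_z = 1))
coupling_spec <- function(effect_vector = numeric(0),
                          ar_coefficient = 0.3,
                          noise_sd = 1,
                          measurement_sd = 0.5) {
  if (length(effect_vector)) {
    if (is.null(names(effect_vector)) || any(names(effect_vector) == ""))
      abort_config("effect_vector", "must be a named numeric vector")
    allowed <- setdiff(feature_variables(), c("mood_lag1", "mood_lag2"))
    bad <- setdiff(names(effect_vector), allowed)
    if (length(bad))
      abort_config("effect_vector",
                   paste0("has names that are not behaviour predictor variables: ",
                          paste(bad, collapse = ", ")))
  }
  if (!is.numeric(ar_coefficient) || length(ar_coefficient) != 1 ||
      is.na(ar_coefficient) || abs(ar_coefficient) >= 1)
    abort_config("ar_coefficient", "must be in (-1, 1)")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || is.na(noise_sd) || noise_sd <= 0)
    abort_config("noise_sd", "must be > 0")
  if (!is.numeric(measurement_sd) || length(measurement_sd) != 1 ||
      is.na(measurement_sd) || measurement_sd <= 0)
    abort_config("measurement_sd", "must be > 0")
  structure(list(effect_vector = effect_vector,
                 ar_coefficient = ar_coefficient,
                 noise_sd = noise_sd,
                 measurement_sd = measurement_sd),
            class = "coupling_spec")
}

#' Synthetic study configuration
#'
#' Describes one simulated data-collection study: how many participants and
#' days, the mood-diary prompting schedule, missingness rates, the size of
#' the contact and app universes, and the latent behaviour-mood coupling.
#'
#' @param n_participants Number of participants.
#' @param n_days Study length in days (>= 8 so the growing-window evaluation
#'   has at least one prediction day).
#' @param ratings_per_day Number of mood prompts per day (>= 1).
#' @param rating_times Clock hours of the prompts; length must equal
#'   `ratings_per_day`.
#' @param seed Integer master seed. Each participant draws from a child seed
#'   offset by their index, so participant `i` is reproducible in isolation.
#' @param missing_day_prob Probability that a participant-day is missing
#'   entirely (no sensor events and no ratings; e.g. phone off).
#' @param missing_rating_prob Probability that an individual prompt goes
#'   unanswered on an otherwise observed day.
#' @param n_contacts,n_apps Size of each participant's contact and app
#'   universes. Interaction propensity is Zipf-distributed so a stable
#'   "top 5" exists.
#' @param coupling A [coupling_spec()].
#' @param study_start Calendar date of study day 1 (ISO date string or Date).
#' @return A list of class `study_config`.
#' @export
#' @examples
#' study_config(n_participants = 2, n_days = 10, seed = 1)
study_config <- function(n_participants = 27,
                         n_days = 42,
                         ratings_per_day = 5,
                         rating_times = c(9, 12, 15, 18, 21),
                         seed = 1,
                         missing_day_prob = 0.05,
                         missing_rating_prob = 0.1,
                         n_contacts = 25,
                         n_apps = 40,
                         coupling = coupling_spec(),
                         study_start = "2016-01-04") {
  n_participants <- check_count(n_participants, "n_participants")
  n_days <- check_count(n_days, "n_days", min = 8)
  ratings_per_day <- check_count(ratings_per_day, "ratings_per_day")
  if (!is.numeric(rating_times) || length(rating_times) != ratings_per_day ||
      any(rating_times < 0 | rating_times >= 24))
    abort_config("rating_times",
                 "must be clock hours in [0, 24) with one entry per rating")
  seed <- check_count(seed, "seed", min = 0)
  check_prob(missing_day_prob, "missing_day_prob")
  check_prob(missing_rating_prob, "missing_rating_prob")
  n_contacts <- check_count(n_contacts, "n_contacts")
  n_apps <- check_count(n_apps, "n_apps")
  if (!inherits(coupling, "coupling_spec"))
    abort_config("coupling", "must be built with coupling_spec()")
  study_start <- as.Date(study_start)
  if (is.na(study_start)) abort_config("study_start", "must be a valid date")
  structure(list(n_participants = n_participants, n_days = n_days,
                 ratings_per_day = ratings_per_day, rating_times = rating_times,
                 seed = seed, missing_day_prob = missing_day_prob,
                 missing_rating_prob = missing_rating_prob,
                 n_contacts = n_contacts, n_apps = n_apps,
                 coupling = coupling, study_start = study_start),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config> ", x$n_participants, " participants x ", x$n_days,
      " days, ", x$ratings_per_day, " ratings/day, seed ", x$seed, "\n", sep = "")
  ev <- x$coupling$effect_vector
  if (length(ev)) {
    cat("  coupling:", paste(sprintf("%s=%.3g", names(ev), ev), collapse = ", "), "\n")
  } else {
    cat("  coupling: none (null model)\n")
  }
  invisible(x)
}
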
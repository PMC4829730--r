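# Fixed vocabulary of the daily predictor table: 13 feature groups expanded
# into 53 named variables. Order is load-bearing -- it is the column order of
# every feature table and the deterministic tie-break order during forward
# selection.

#' App category vocabulary
#'
#' The eleven app categories used for the categorized app-usage histograms.
#' Apps without a known category map to `"unknown"`.
#'
#' @return Character vector of length 11.
#' @export
#' @examples
#' app_category_levels()
app_category_levels <- function() {
  c("built-in", "communication", "entertainment", "finance", "games",
    "office", "social", "travel", "utilities", "other", "unknown")
}

# category names made syntactic for use in column names
cat_slug <- function(x) gsub("-", "_", x, fixed = TRUE)

#' The daily predictor schema
#'
#' Returns the ordered set of 53 predictor variables, grouped into 13
#' features: normalized 3-day histograms of call frequency and call duration
#' with the five most-contacted persons, the same for SMS frequency; the
#' daily high-activity fraction from the accelerometer; within-participant
#' z-scores of daily screen-on counts and total screen time; normalized
#' 3-day histograms of top-5 app frequency and duration and of the 11 app
#' categories (frequency and duration); the max-normalized daily photo
#' count; and lag-1/lag-2 values of the standardized mood target.
#'
#' @return A tibble with columns `variable` (53 unique names, fixed order),
#'   `feature` (one of 13 group labels) and `block` (calls_sms, activity,
#'   screen, apps, images, mood_history).
#' @export
#' @examples
#' feature_schema()
#' dplyr::count(feature_schema(), block)
feature_schema <- function() {
  cats <- cat_slug(app_category_levels())
  groups <- list(
    call_top5_freq = list(paste0("call_top5_freq_", 1:5), "calls_sms"),
    call_top5_dur  = list(paste0("call_top5_dur_",  1:5), "calls_sms"),
    sms_top5_freq  = list(paste0("sms_top5_freq_",  1:5), "calls_sms"),
    activity_high_pct = list("activity_high_pct", "activity"),
    screen_freq_z  = list("screen_freq_z", "screen"),
    screen_dur_z   = list("screen_dur_z",  "screen"),
    app_top5_freq  = list(paste0("app_top5_freq_", 1:5), "apps"),
    app_top5_dur   = list(paste0("app_top5_dur_",  1:5), "apps"),
    app_cat_freq   = list(paste0("app_cat_freq_", cats), "apps"),
    app_cat_dur    = list(paste0("app_cat_dur_",  cats), "apps"),
    images_norm    = list("images_norm", "images"),
    mood_lag1      = list("mood_lag1", "mood_history"),
    mood_lag2      = list("mood_lag2", "mood_history")
  )
  tibble::tibble(
    variable = unlist(lapply(groups, `[[`, 1), use.names = FALSE),
    feature = rep(names(groups), vapply(groups, function(g) length(g[[1]]), 1L)),
    block = rep(vapply(groups, `[[`, "", 2), vapply(groups, function(g) length(g[[1]]), 1L))
  )
}

#' @rdname feature_schema
#' @export
feature_variables <- function() feature_schema()$variable
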
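# Plain-CSV persistence of a study bundle: one directory per participant
# holding the six sensor streams plus the mood diary, and a shared app
# category lookup at the top level. Timestamps are written as ISO-8601
# (UTC); re-reading reproduces the in-memory streams exactly.

stream_files <- function() {
  c(calls = "calls.csv", sms = "sms.csv", screen = "screen.csv",
    apps = "apps.csv", camera = "camera.csv", activity = "activity.csv",
    mood = "mood.csv")
}

iso_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

write_atomic_csv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_csv(df, tmp, progress = FALSE)
  if (!file.rename(tmp, path))
    rlang::abort(sprintf("I/O failure writing %s", path))
  invisible(path)
}

#' Write study streams to CSV
#'
#' Writes one subdirectory per participant with `calls.csv`, `sms.csv`,
#' `screen.csv`, `apps.csv`, `camera.csv`, `activity.csv` and `mood.csv`
#' (7 files per participant), plus a shared `app_categories.csv`, all UTF-8
#' with a header row and ISO-8601 timestamps. Files are written atomically
#' (temp file + rename).
#'
#' @param study A `mood_study` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_streams <- function(study, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    rlang::abort(sprintf("I/O failure: cannot create directory %s", dir))
  pids <- sprintf("p%03d", seq_len(study$config$n_participants))
  for (pid in pids) {
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    for (nm in names(stream_files())) {
      df <- study[[if (nm == "mood") "mood" else nm]]
      df <- df[df$participant_id == pid, , drop = FALSE]
      df$participant_id <- NULL
      tcol <- if (nm == "activity") "hour_start" else "timestamp"
      df[[tcol]] <- iso_ts(df[[tcol]])
      write_atomic_csv(df, file.path(pdir, stream_files()[[nm]]))
    }
  }
  write_atomic_csv(study$app_categories, file.path(dir, "app_categories.csv"))
  invisible(dir)
}

stream_col_types <- function() {
  list(
    calls = readr::cols(timestamp = readr::col_datetime(),
                        direction = readr::col_character(),
                        contact_id = readr::col_character(),
                        duration_s = readr::col_double()),
    sms = readr::cols(timestamp = readr::col_datetime(),
                      contact_id = readr::col_character()),
    screen = readr::cols(timestamp = readr::col_datetime(),
                         state = readr::col_character()),
    apps = readr::cols(timestamp = readr::col_datetime(),
                       app_id = readr::col_character(),
                       duration_s = readr::col_double()),
    camera = readr::cols(timestamp = readr::col_datetime()),
    activity = readr::cols(hour_start = readr::col_datetime(),
                           fraction_high = readr::col_double(),
                           n_samples = readr::col_integer()),
    mood = readr::cols(timestamp = readr::col_datetime(),
                       mood = readr::col_integer(),
                       valence = readr::col_integer(),
                       arousal = readr::col_integer())
  )
}

#' Read study streams from CSV
#'
#' Inverse of [write_streams()]: reassembles the stacked stream tibbles from
#' a directory of per-participant CSVs. The study configuration is not
#' stored on disk; pass the one used for generation (or a compatible one
#' describing the window) to obtain a full `mood_study`.
#'
#' @param dir Directory written by [write_streams()].
#' @param config The [study_config()] describing the study window.
#' @return A `mood_study` (without the generator's latent ground truth).
#' @export
read_streams <- function(dir, config) {
  if (!dir.exists(dir))
    rlang::abort(sprintf("I/O failure: no such directory %s", dir))
  pdirs <- sort(list.dirs(dir, recursive = FALSE))
  types <- stream_col_types()
  out <- lapply(names(stream_files()), function(nm) {
    purrr::list_rbind(lapply(pdirs, function(pdir) {
      df <- readr::read_csv(file.path(pdir, stream_files()[[nm]]),
                            col_types = types[[nm]], progress = FALSE)
      tcol <- if (nm == "activity") "hour_start" else "timestamp"
      attr(df[[tcol]], "tzone") <- "UTC"
      dplyr::mutate(df, participant_id = basename(pdir), .before = 1)
    }))
  })
  names(out) <- names(stream_files())
  lookup <- readr::read_csv(file.path(dir, "app_categories.csv"),
                            col_types = readr::cols(
                              app_id = readr::col_character(),
                              category = readr::col_character()),
                            progress = FALSE)
  structure(c(list(config = config), out, list(app_categories = lookup)),
            class = "mood_study")
}
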
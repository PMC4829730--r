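# End-to-end orchestration: simulate -> daily targets -> feature tables ->
# model fitting + evaluation -> report, from a single configuration, with
# atomic file writes and a MANIFEST recording each completed stage.

#' Run the full pipeline
#'
#' Executes every stage on one synthetic study: generation, daily
#' aggregation and within-participant standardization of the mood targets,
#' participant pruning, feature building per target measure, full-data
#' leave-one-out evaluation of each model family, benchmark comparisons,
#' the incremental assessment, and a Markdown report. All randomness flows
#' from `config$seed`, so outputs are a pure function of the
#' configuration; two runs with the same config produce byte-identical
#' files.
#'
#' Written to `out_dir`: `daily_targets.csv`, `adherence.csv`,
#' `features_<measure>.csv`, `models.jsonl` (full-data fits, one JSON
#' record per participant x measure x family), `predictions.csv`,
#' `performance.csv`, `comparisons.csv`, `incremental.csv`,
#' `incremental_trend.csv`, `report.md`, `MANIFEST`. Files are written via
#' temp-file + rename; on failure the MANIFEST names the failed stage.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed). `NULL` skips all
#'   file output and just returns the results.
#' @param measures Target measures to evaluate.
#' @param families Model families to evaluate.
#' @param margin Tolerated error margin on the standardized scale.
#' @param min_days Pruning threshold: minimum complete days for inclusion.
#' @param window Feature histogram window (days).
#' @param incremental Run the growing-window assessment too?
#' @param verbose Log per-stage timing to stderr?
#' @return (Invisibly) a list: `study`, `targets`, `adherence`, `features`
#'   (per measure), `predictions`, `performance`, `comparisons`,
#'   `incremental` (per measure), `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         measures = c("mood", "valence", "arousal"),
                         families = model_families(),
                         margin = 0.5, min_days = 20, window = 3,
                         incremental = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  done <- character(0)
  say <- function(stage) {
    if (verbose)
      message(sprintf("[%7.2fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                      stage))
  }
  emit <- function(df, file) {
    if (!is.null(out_dir)) write_atomic_csv(df, file.path(out_dir, file))
  }
  finish_manifest <- function(failed = NULL) {
    if (is.null(out_dir)) return(invisible())
    lines <- c(sprintf("seed: %d", config$seed),
               sprintf("stage_completed: %s", done),
               if (!is.null(failed)) sprintf("stage_failed: %s", failed))
    tmp <- file.path(out_dir, "MANIFEST.tmp")
    writeLines(lines, tmp)
    file.rename(tmp, file.path(out_dir, "MANIFEST"))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  res <- tryCatch({
    say("simulate")
    study <- simulate_study(config)
    done <- c(done, "simulate")

    say("targets")
    targets <- aggregate_daily(study$mood, config$study_start) |>
      standardize_targets()
    emit(targets, "daily_targets.csv")
    done <- c(done, "targets")

    say("features")
    features <- lapply(stats::setNames(measures, measures), function(m)
      build_feature_table(study, targets, m, window))
    adherence <- prune_participants(targets, features[[1]], min_days)
    emit(adherence, "adherence.csv")
    included <- adherence$participant_id[adherence$included]
    features <- lapply(features, function(f) {
      out <- f[f$participant_id %in% included, , drop = FALSE]
      attr(out, "measure") <- attr(f, "measure")
      out
    })
    if (!is.null(out_dir))
      for (m in measures)
        emit(features[[m]], sprintf("features_%s.csv", m))
    done <- c(done, "features")

    say("models")
    model_records <- list()
    for (m in measures) {
      rows <- features[[m]][features[[m]]$modelable, , drop = FALSE]
      for (pid in included) {
        d <- rows[rows$participant_id == pid, , drop = FALSE]
        for (fam in families) {
          if (nrow(d) < min_rows_for(fam)) next
          fit <- fit_family(d, "target", fam)
          model_records[[length(model_records) + 1]] <- list(
            participant_id = pid, measure = m, family = fam,
            n_train = fit$n_train, intercept = fit$intercept,
            coefficients = as.list(fit$coefficients),
            trace = if (is.null(fit$trace)) NULL else
              lapply(seq_len(nrow(fit$trace)), function(i)
                list(variable = fit$trace$variable[i],
                     criterion = fit$trace$criterion[i])))
        }
      }
    }
    if (!is.null(out_dir)) {
      tmp <- file.path(out_dir, "models.jsonl.tmp")
      writeLines(vapply(model_records, function(r)
        jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null"),
        character(1)), tmp)
      file.rename(tmp, file.path(out_dir, "models.jsonl"))
    }
    done <- c(done, "models")

    say("loocv")
    predictions <- purrr::list_rbind(lapply(measures, function(m)
      purrr::list_rbind(lapply(families, function(fam)
        loocv_evaluate(features[[m]], fam, margin)))))
    perf <- participant_performance(predictions)
    emit(predictions, "predictions.csv")
    emit(perf, "performance.csv")
    done <- c(done, "loocv")

    say("comparisons")
    pers <- intersect(families, c("stepAIC", "stepCV"))
    bench <- intersect(families, c("mean", "history"))
    comparisons <- purrr::list_rbind(lapply(pers, function(a)
      purrr::list_rbind(lapply(bench, function(b)
        purrr::list_rbind(lapply(c("cv_mse", "pct_correct"), function(met)
          compare_families(perf, a, b, met)))))))
    if (nrow(comparisons)) emit(comparisons, "comparisons.csv")
    done <- c(done, "comparisons")

    inc <- NULL
    if (incremental) {
      say("incremental")
      inc <- lapply(stats::setNames(measures, measures), function(m)
        incremental_evaluate(features[[m]], families, margin))
      daily_all <- purrr::list_rbind(Map(
        function(x, m) dplyr::mutate(x$daily, measure = m, .before = 1),
        inc, names(inc)))
      emit(daily_all, "incremental.csv")
      emit(purrr::list_rbind(lapply(inc, `[[`, "trend")), "incremental_trend.csv")
      done <- c(done, "incremental")
    }

    say("report")
    report <- summarize_report(perf, comparisons, inc)
    if (!is.null(out_dir)) {
      tmp <- file.path(out_dir, "report.md.tmp")
      writeLines(render_report_md(report, config), tmp)
      file.rename(tmp, file.path(out_dir, "report.md"))
    }
    done <- c(done, "report")
    finish_manifest()
    say("done")
    list(study = study, targets = targets, adherence = adherence,
         features = features, predictions = predictions, performance = perf,
         comparisons = comparisons, incremental = inc, report = report)
  }, error = function(e) {
    finish_manifest(failed = setdiff(
      c("simulate", "targets", "features", "models", "loocv", "comparisons",
        "incremental", "report"), done)[1])
    rlang::abort("pipeline stage failed; partial outputs retained",
                 parent = e)
  })
  invisible(res)
}

fmt <- function(x, d = 4) formatC(x, digits = d, format = "f")

render_report_md <- function(report, config) {
  tab <- report$performance_table
  lines <- c(
    "# Mood prediction pipeline report", "",
    sprintf("Study: %d participants x %d days (seed %d).",
            config$n_participants, config$n_days, config$seed), "",
    "## Predictive performance (mean across participants, 95% CI)", "",
    "| measure | family | n | % correct | cv MSE |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %d | %s (%s-%s) | %s (%s-%s) |",
            tab$measure, tab$family, tab$n_participants,
            fmt(tab$mean_pct_correct, 1), fmt(tab$pct_correct_lo, 1),
            fmt(tab$pct_correct_hi, 1), fmt(tab$mean_cv_mse),
            fmt(tab$cv_mse_lo), fmt(tab$cv_mse_hi)))
  cmp <- report$comparisons
  if (!is.null(cmp) && nrow(cmp)) {
    lines <- c(lines, "", "## Benchmark comparisons (Wilcoxon signed-rank)",
               "",
               "| measure | comparison | metric | V | p | n |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s vs %s | %s | %s | %s | %d |",
                       cmp$measure, cmp$family_a, cmp$family_b, cmp$metric,
                       fmt(cmp$statistic, 1), fmt(cmp$p_value), cmp$n_pairs))
  }
  tr <- report$incremental_trend
  if (!is.null(tr) && nrow(tr)) {
    lines <- c(lines, "", "## Incremental trend (difference to mean model)",
               "",
               "| measure | family | metric | intercept (SE) | study day (SE) |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s (%s) | %s (%s) |",
                       tr$measure, tr$family, tr$metric,
                       fmt(tr$intercept_estimate), fmt(tr$intercept_se),
                       fmt(tr$slope_estimate), fmt(tr$slope_se)))
  }
  lines
}
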
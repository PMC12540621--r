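#' Preprocess one session of gaze recordings into trial results
#'
#' For each trial: computes quality metrics ([trial_qc()]), classifies
#' fixations ([classify_fixations()]), extracts the SRT ([extract_srt()]),
#' then applies the exclusion cascade ([apply_filters()]).
#'
#' @param gaze_list Named list of per-trial gaze data.frames (names =
#'   trial ids), as from [simulate_session_gaze()] or [read_gaze_tsv()].
#' @param schedule The session's [schedule_session()] schedule.
#' @param task A [task_spec()].
#' @param params A [fixation_params()].
#' @param thresholds A [filter_thresholds()].
#' @return A list with `results` (final trial results) and `qc` (per-trial
#'   quality metrics).
#' @export
preprocess_session <- function(gaze_list, schedule, task = task_spec(),
                               params = fixation_params(),
                               thresholds = filter_thresholds()) {
  stopifnot(all(schedule$trial_id %in% names(gaze_list)))
  qc <- do.call(rbind, lapply(schedule$trial_id, function(id) {
    cbind(trial_id = id, trial_qc(gaze_list[[id]]))
  }))
  results <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(i) {
    g <- gaze_list[[schedule$trial_id[i]]]
    fx <- classify_fixations(g, params)
    extract_srt(fx, schedule[i, ], task)
  }))
  results <- apply_filters(results, qc, thresholds)
  list(results = results, qc = qc)
}

#' Exclusion audit table
#'
#' Counts trials per final status (mirroring a per-step removal overview).
#'
#' @param results Trial results with a `status` column; optionally a
#'   grouping column.
#' @param by Optional name of a grouping column (e.g. `"wave_label"`).
#' @return Data.frame of counts per status (per group).
#' @export
filter_audit <- function(results, by = NULL) {
  lev <- c("ok", "excl_precision", "excl_data_loss", "excl_no_movement",
           "excl_wrong_side", "excl_premature", "excl_too_slow")
  f <- factor(results$status, levels = lev)
  if (is.null(by)) {
    as.data.frame(table(status = f), responseName = "n")
  } else {
    as.data.frame(table(group = results[[by]], status = f),
                  responseName = "n")
  }
}

#' Simulate and preprocess a whole cohort end to end
#'
#' For every participant-wave measurement in a [build_cohort()] table:
#' schedules a session, simulates its gaze streams from the participant's
#' latent profile, preprocesses them, and summarises the retained trials
#' into condition medians and difference scores. Gaze data are processed in
#' memory measurement by measurement.
#'
#' @param cohort A [build_cohort()] table (needs the `profile` list-column).
#' @param task A [task_spec()].
#' @param params A [fixation_params()].
#' @param thresholds A [filter_thresholds()].
#' @param min_trials Minimum retained trials per condition for a median.
#' @param seed Optional integer seed covering the whole run.
#' @return A list: `summaries` (one row per measurement, as from
#'   [summarize_participant()], plus the cohort's latent truth columns),
#'   `audit` (exclusion counts per wave), and `truth` (per-trial hidden
#'   labels with matched final statuses, for generator-validation tests).
#' @export
preprocess_cohort <- function(cohort, task = task_spec(),
                              params = fixation_params(),
                              thresholds = filter_thresholds(),
                              min_trials = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  summaries <- vector("list", n)
  audits <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- schedule_session(task)
    sim <- simulate_session_gaze(sched, cohort$profile[[i]],
                                 cohort$age_months[i], task)
    pp <- preprocess_session(sim$gaze, sched, task, params, thresholds)
    ok <- pp$results[pp$results$status == "ok", ]
    summaries[[i]] <- summarize_participant(
      ok, min_trials = min_trials,
      participant_id = cohort$participant_id[i],
      wave_label = cohort$wave_label[i],
      age_months = cohort$age_months[i])
    audits[[i]] <- cbind(wave_label = cohort$wave_label[i],
                         filter_audit(pp$results))
    tr <- sim$truth
    tr$status <- pp$results$status[match(tr$trial_id, pp$results$trial_id)]
    tr$participant_id <- cohort$participant_id[i]
    truths[[i]] <- tr
  }
  summaries <- do.call(rbind, summaries)
  truth_cols <- intersect(c("mu_scale", "gap_scale", "fac_scale", "true_mu_ms",
                            "true_gap_effect_ms", "true_facilitation_ms"),
                          names(cohort))
  summaries <- cbind(summaries, cohort[truth_cols])
  audit <- do.call(rbind, audits)
  audit <- stats::aggregate(n ~ wave_label + status, data = audit, FUN = sum)
  list(summaries = summaries, audit = audit,
       truth = do.call(rbind, truths))
}
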
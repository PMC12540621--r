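#' Assign fixation centroids to screen areas of interest
#'
#' The screen is divided into three equal-width vertical bands (left, center,
#' right). Intervals are left-closed/right-open, so a centroid exactly on the
#' left/center boundary is `center` and one exactly on the center/right
#' boundary is `right`. Centroids outside the screen are clamped to its
#' edge. Band edges are configurable.
#'
#' @param x_deg Numeric vector of horizontal centroid positions, degrees from
#'   screen center (positive rightward).
#' @param task A [task_spec()] providing the screen width.
#' @param edges Length-2 numeric, the left/center and center/right band
#'   boundaries; default `c(-width/6, width/6)` (equal thirds).
#' @return Character vector in `{"left", "center", "right"}`.
#' @export
#' @examples
#' assign_aoi(c(-15, 0, 15), task_spec())
assign_aoi <- function(x_deg, task = task_spec(), edges = NULL) {
  half <- task$screen_width_deg / 2
  if (is.null(edges)) edges <- c(-task$screen_width_deg / 6,
                                 task$screen_width_deg / 6)
  stopifnot(length(edges) == 2L, edges[1] < edges[2])
  x <- pmin(pmax(x_deg, -half), half)
  ifelse(x < edges[1], "left", ifelse(x < edges[2], "center", "right"))
}

#' Extract the saccadic reaction time from classified fixations
#'
#' Scans the time-ordered fixations for the first center-AOI fixation
#' immediately followed by a left- or right-AOI fixation. The SRT is the end
#' time of that center fixation (the last moment of fixation on the center)
#' minus the peripheral stimulus onset; the side of first orienting is the
#' AOI of the following fixation. When multiple center-to-side instances
#' occur, the first is used. Without any such pair the trial is marked
#' `excl_no_movement`.
#'
#' The returned status is pre-filter: quality and reaction-time filters are
#' applied afterwards by [apply_filters()].
#'
#' @param fixations A [classify_fixations()] table.
#' @param schedule One row of a [schedule_session()] schedule.
#' @param task A [task_spec()].
#' @return One-row data.frame: `trial_id`, `condition`, `side`
#'   (scheduled side), `side_of_first_orienting`, `srt_ms`, `status`.
#' @export
extract_srt <- function(fixations, schedule, task = task_spec()) {
  if (is.data.frame(schedule)) {
    stopifnot(nrow(schedule) == 1L)
    schedule <- as.list(schedule)
  }
  res <- data.frame(trial_id = schedule$trial_id,
                    condition = schedule$condition,
                    side = schedule$side,
                    side_of_first_orienting = "none",
                    srt_ms = NA_real_,
                    status = "excl_no_movement",
                    stringsAsFactors = FALSE)
  if (is.null(fixations) || nrow(fixations) < 2L) return(res)
  aoi <- assign_aoi(fixations$centroid_x_deg, task)
  k <- nrow(fixations)
  hit <- which(aoi[-k] == "center" & aoi[-1] %in% c("left", "right"))
  if (length(hit) == 0L) return(res)
  i <- hit[1L]
  res$side_of_first_orienting <- aoi[i + 1L]
  res$srt_ms <- fixations$end_ms[i] - schedule$peripheral_onset_ms
  res$status <- "ok"
  res
}

#' Quality and reaction-time filter thresholds
#'
#' @param rms_max Maximum RMS-S2S precision, degrees (trials above are
#'   removed; the boundary value is retained).
#' @param loss_max Maximum proportion of data loss (strict).
#' @param rt_min,rt_max Retained SRT range, ms: below `rt_min` is a premature
#'   saccade, above `rt_max` indicates inattentiveness or failed
#'   disengagement (both strict; the boundary values are retained).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(rms_max = 2.0, loss_max = 0.7,
                              rt_min = 150, rt_max = 2000) {
  stopifnot(rms_max > 0, loss_max >= 0, loss_max <= 1, rt_min >= 0,
            rt_max > rt_min)
  structure(list(rms_max = rms_max, loss_max = loss_max,
                 rt_min = rt_min, rt_max = rt_max),
            class = "filter_thresholds")
}

#' Apply the trial-exclusion cascade
#'
#' Filters are applied in order; each trial receives the first applicable
#' exclusion status: (1) precision worse than `rms_max` (or unmeasurable) —
#' `excl_precision`; (2) data loss above `loss_max` — `excl_data_loss`;
#' (3) no center-to-side fixation sequence — `excl_no_movement`; (4) first
#' orienting to the unscheduled side — `excl_wrong_side`; (5) SRT below
#' `rt_min` — `excl_premature`; (6) SRT above `rt_max` — `excl_too_slow`.
#' All comparisons are strict, so boundary values (e.g. RMS exactly 2.0, SRT
#' exactly 150 or 2000 ms) are retained.
#'
#' @param results Trial results from [extract_srt()] (one row per trial).
#' @param qc Matching quality table with `trial_id`, `rms_s2s_deg`,
#'   `data_loss_prop`.
#' @param thresholds A [filter_thresholds()].
#' @return `results` with final `status` values.
#' @export
apply_filters <- function(results, qc, thresholds = filter_thresholds()) {
  stopifnot(all(results$trial_id %in% qc$trial_id))
  qc <- qc[match(results$trial_id, qc$trial_id), ]
  status <- rep("ok", nrow(results))
  no_move <- results$status == "excl_no_movement" | is.na(results$srt_ms)
  wrong <- !no_move & results$side_of_first_orienting != results$side
  premature <- !no_move & results$srt_ms < thresholds$rt_min
  too_slow <- !no_move & results$srt_ms > thresholds$rt_max
  status[too_slow] <- "excl_too_slow"
  status[premature] <- "excl_premature"
  status[wrong] <- "excl_wrong_side"
  status[no_move] <- "excl_no_movement"
  status[qc$data_loss_prop > thresholds$loss_max] <- "excl_data_loss"
  status[is.na(qc$rms_s2s_deg) | qc$rms_s2s_deg > thresholds$rms_max] <- "excl_precision"
  results$status <- status
  results
}

#' Per-participant condition medians and difference scores
#'
#' From a participant's retained (status `ok`) trials, computes the median
#' SRT per condition — absent when fewer than `min_trials` trials remain in
#' that condition — and the two difference scores: the gap effect (median
#' overlap SRT minus median gap SRT, the attentional disengagement cost) and
#' the facilitation effect (median baseline SRT minus median gap SRT).
#' Even-count medians are the midpoint of the two central values.
#'
#' @param valid_trials Trial results with `condition` and `srt_ms`, all
#'   status `ok`.
#' @param min_trials Minimum retained trials per condition (default 4).
#' @param participant_id,wave_label,age_months Carried through to the output.
#' @return One-row data.frame: per-condition `n_valid_*` and `median_*_ms`,
#'   plus `gap_effect_ms` and `facilitation_ms` (`NA` when a needed median is
#'   absent).
#' @export
summarize_participant <- function(valid_trials, min_trials = 4,
                                  participant_id = NA_character_,
                                  wave_label = NA_character_,
                                  age_months = NA_real_) {
  if (nrow(valid_trials) > 0 && any(valid_trials$status != "ok")) {
    stop("summarize_participant: all input trials must have status 'ok'")
  }
  cond_med <- function(cond) {
    srt <- valid_trials$srt_ms[valid_trials$condition == cond]
    list(n = length(srt),
         med = if (length(srt) >= min_trials) stats::median(srt) else NA_real_)
  }
  g <- cond_med("gap"); o <- cond_med("overlap"); b <- cond_med("baseline")
  data.frame(participant_id = participant_id,
             wave_label = wave_label,
             age_months = age_months,
             n_valid_gap = g$n, n_valid_overlap = o$n, n_valid_baseline = b$n,
             median_gap_ms = g$med, median_overlap_ms = o$med,
             median_baseline_ms = b$med,
             gap_effect_ms = o$med - g$med,
             facilitation_ms = b$med - g$med,
             stringsAsFactors = FALSE)
}

#' Flag age-window violations in a cohort table
#'
#' Participants whose age at a wave falls outside that wave's configured age
#' bounds, or inside the *next* wave's bounds (overlap with the consecutive
#' time bin), are flagged — not silently dropped; exclusion is applied
#' downstream by filtering on `wave_ok`.
#'
#' @param cohort Data.frame with `wave_label` and `age_months`.
#' @param waves Wave table as in [default_waves()].
#' @return `cohort` with added logical columns `age_out_of_bounds`,
#'   `age_overlaps_next`, `wave_ok`.
#' @export
validate_wave_assignment <- function(cohort, waves = default_waves()) {
  idx <- match(cohort$wave_label, waves$label)
  if (anyNA(idx)) {
    stop("validate_wave_assignment: unknown wave label(s): ",
         paste(unique(cohort$wave_label[is.na(idx)]), collapse = ", "))
  }
  lo <- waves$age_lo_months[idx]
  hi <- waves$age_hi_months[idx]
  nxt <- idx + 1L
  has_next <- nxt <= nrow(waves)
  nlo <- ifelse(has_next, waves$age_lo_months[pmin(nxt, nrow(waves))], Inf)
  nhi <- ifelse(has_next, waves$age_hi_months[pmin(nxt, nrow(waves))], -Inf)
  cohort$age_out_of_bounds <- cohort$age_months < lo | cohort$age_months > hi
  cohort$age_overlaps_next <- has_next & cohort$age_months >= nlo &
    cohort$age_months <= nhi
  cohort$wave_ok <- !(cohort$age_out_of_bounds | cohort$age_overlaps_next)
  cohort
}
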
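fx_row <- function(start, end, x, n = 30L) {
  data.frame(start_ms = start, end_ms = end, centroid_x_deg = x,
             centroid_y_deg = 0, n_samples = n)
}

test_that("AOI bands split the screen into left-closed thirds", {
  task <- task_spec()  # width 51 -> boundaries at -8.5 and 8.5
  expect_equal(assign_aoi(0, task), "center")
  expect_equal(assign_aoi(-task$screen_width_deg / 3, task), "left")
  expect_equal(assign_aoi(task$screen_width_deg / 3, task), "right")
  # boundary values fall into the band to their right (left-closed)
  expect_equal(assign_aoi(-task$screen_width_deg / 6, task), "center")
  expect_equal(assign_aoi(task$screen_width_deg / 6, task), "right")
  # off-screen centroids are clamped
  expect_equal(assign_aoi(-1000, task), "left")
  expect_equal(assign_aoi(1000, task), "right")
})

test_that("SRT is the center-fixation end minus peripheral onset", {
  sched <- make_schedule_row(side = "right", peripheral_onset_ms = 1000)
  fx <- rbind(fx_row(0, 1250, 0), fx_row(1300, 2000, 20))
  res <- extract_srt(fx, sched, task_spec())
  expect_equal(res$srt_ms, 250)
  expect_equal(res$side_of_first_orienting, "right")
  expect_equal(res$status, "ok")
})

test_that("all-center fixations mean no orienting movement", {
  sched <- make_schedule_row()
  fx <- rbind(fx_row(0, 900, 0), fx_row(950, 2000, 1))
  res <- extract_srt(fx, sched, task_spec())
  expect_equal(res$status, "excl_no_movement")
  expect_true(is.na(res$srt_ms))
  expect_equal(res$side_of_first_orienting, "none")
  expect_equal(extract_srt(fx[0, ], sched, task_spec())$status,
               "excl_no_movement")
})

test_that("with two center-to-side sequences the first instance is used", {
  sched <- make_schedule_row(side = "right", peripheral_onset_ms = 1000)
  fx <- rbind(fx_row(0, 1200, 0), fx_row(1250, 1600, 20),
              fx_row(1650, 1900, 0), fx_row(1950, 2300, 20))
  res <- extract_srt(fx, sched, task_spec())
  expect_equal(res$srt_ms, 200)
})

test_that("the filter cascade applies thresholds strictly and in order", {
  sched <- make_schedule_row(side = "right", peripheral_onset_ms = 1000)
  base <- extract_srt(rbind(fx_row(0, 1250, 0), fx_row(1300, 2000, 20)),
                      sched, task_spec())
  qc_clean <- data.frame(trial_id = "T001", rms_s2s_deg = 0.3,
                         data_loss_prop = 0.1)
  qc_of <- function(rms, loss) data.frame(trial_id = "T001",
                                          rms_s2s_deg = rms,
                                          data_loss_prop = loss)

  # premature saccade
  r <- base; r$srt_ms <- 100
  expect_equal(apply_filters(r, qc_clean)$status, "excl_premature")
  # slow response
  r <- base; r$srt_ms <- 2100
  expect_equal(apply_filters(r, qc_clean)$status, "excl_too_slow")
  # wrong side
  r <- base; r$side_of_first_orienting <- "left"
  expect_equal(apply_filters(r, qc_clean)$status, "excl_wrong_side")
  # poor precision dominates everything else
  r <- base; r$srt_ms <- 100
  expect_equal(apply_filters(r, qc_of(2.5, 0.1))$status, "excl_precision")
  expect_equal(apply_filters(base, qc_of(NA, 0.1))$status, "excl_precision")
  # data loss
  expect_equal(apply_filters(base, qc_of(0.3, 0.8))$status, "excl_data_loss")
  # boundary values are retained (strict inequalities)
  r <- base; r$srt_ms <- 150
  expect_equal(apply_filters(r, qc_of(2.0, 0.7))$status, "ok")
  r$srt_ms <- 2000
  expect_equal(apply_filters(r, qc_of(2.0, 0.7))$status, "ok")
})

test_that("threshold tightening never increases the retained-trial count", {
  set.seed(61)
  n <- 300
  results <- data.frame(
    trial_id = sprintf("T%03d", 1:n),
    condition = sample(c("gap", "overlap", "baseline"), n, TRUE),
    side = "right",
    side_of_first_orienting = sample(c("right", "left"), n, TRUE, c(0.8, 0.2)),
    srt_ms = runif(n, -100, 2500),
    status = "ok", stringsAsFactors = FALSE)
  qc <- data.frame(trial_id = results$trial_id,
                   rms_s2s_deg = runif(n, 0, 3),
                   data_loss_prop = runif(n))
  n_ok <- function(th) sum(apply_filters(results, qc, th)$status == "ok")
  base_n <- n_ok(filter_thresholds())
  for (th in list(filter_thresholds(rms_max = 1.5),
                  filter_thresholds(loss_max = 0.5),
                  filter_thresholds(rt_min = 300),
                  filter_thresholds(rt_max = 1500))) {
    expect_lte(n_ok(th), base_n)
  }
})

test_that("participant summaries honour the minimum-trial rule and identities", {
  mk <- function(cond, srt) data.frame(trial_id = paste0(cond, seq_along(srt)),
                                       condition = cond, side = "right",
                                       side_of_first_orienting = "right",
                                       srt_ms = srt, status = "ok",
                                       stringsAsFactors = FALSE)
  trials <- rbind(mk("gap", c(380, 400, 410, 420)),
                  mk("overlap", c(480, 500, 510, 530)),
                  mk("baseline", c(390, 410, 430, 450)))
  s <- summarize_participant(trials)
  expect_equal(s$median_gap_ms, 405)      # even count -> midpoint
  expect_equal(s$median_overlap_ms, 505)
  expect_equal(s$gap_effect_ms, 100)
  expect_equal(s$facilitation_ms, 15)

  # < 4 gap trials: gap median and both effects absent
  s2 <- summarize_participant(rbind(mk("gap", c(380, 400, 410)),
                                    mk("overlap", c(480, 500, 510, 530)),
                                    mk("baseline", c(390, 410, 430, 450))))
  expect_true(is.na(s2$median_gap_ms))
  expect_true(is.na(s2$gap_effect_ms))
  expect_true(is.na(s2$facilitation_ms))
  expect_equal(s2$n_valid_gap, 3)

  # identical SRT multisets -> both effects exactly 0
  srt <- c(400, 420, 440, 460, 480)
  s3 <- summarize_participant(rbind(mk("gap", srt), mk("overlap", srt),
                                    mk("baseline", srt)))
  expect_equal(s3$gap_effect_ms, 0)
  expect_equal(s3$facilitation_ms, 0)

  expect_error(summarize_participant(
    within(mk("gap", c(1, 2, 3, 4)), status <- "excl_premature")), "ok")
})

test_that("wave-assignment validation flags bound and overlap violations", {
  coh <- data.frame(
    participant_id = c("A", "B", "C", "D"),
    wave_label = c("5mo", "5mo", "5mo", "12y"),
    age_months = c(9, 5, 8, 150),   # 9: out of bounds; 8: also in next wave
    stringsAsFactors = FALSE)
  v <- validate_wave_assignment(coh)
  expect_true(v$age_out_of_bounds[1])
  expect_false(v$wave_ok[1])
  expect_true(v$wave_ok[2])
  expect_true(v$age_overlaps_next[3])
  expect_false(v$wave_ok[3])
  expect_true(v$wave_ok[4])   # last wave has no successor
  expect_error(validate_wave_assignment(
    data.frame(participant_id = "X", wave_label = "99y", age_months = 1)),
    "unknown wave")
})
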
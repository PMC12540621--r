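# Shared fixture builders for the test suite.

# a quiet, loss-free, contaminant-free profile for exact-recovery checks
clean_profile <- function(...) {
  latent_profile("Pclean", noise_rms_deg = 0, data_loss_prob = 0,
                 premature_prob = 0, wrong_dir_prob = 0, no_move_prob = 0, ...)
}

# hand-built gaze recording: both eyes identical, all valid, given x/y tracks
make_gaze <- function(x, y = rep(0, length(x)), rate_hz = 300,
                      l_valid = rep(TRUE, length(x)),
                      r_valid = rep(TRUE, length(x)), trial_id = "T001") {
  t_ms <- (seq_along(x) - 1) * 1000 / rate_hz
  lx <- ifelse(l_valid, x, NA_real_)
  ly <- ifelse(l_valid, y, NA_real_)
  rx <- ifelse(r_valid, x, NA_real_)
  ry <- ifelse(r_valid, y, NA_real_)
  data.frame(trial_id = trial_id, t_ms = t_ms,
             lx_deg = lx, ly_deg = ly, rx_deg = rx, ry_deg = ry,
             l_valid = l_valid, r_valid = r_valid,
             stringsAsFactors = FALSE)
}

# one-row schedule for direct trial-level calls
make_schedule_row <- function(condition = "baseline", side = "right",
                              peripheral_onset_ms = 1000, trial_id = "T001") {
  data.frame(trial_id = trial_id, block_index = 1L, condition = condition,
             side = side, center_onset_ms = 0,
             center_offset_ms = peripheral_onset_ms,
             peripheral_onset_ms = peripheral_onset_ms,
             stringsAsFactors = FALSE)
}

# small cohort for statistics tests
small_cohort <- function(n_per_wave = c(30, 30, 20, 10, 20, 10), seed = 1,
                         ...) {
  build_cohort(cohort_spec(n_per_wave = n_per_wave, seed = seed), ...)
}
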
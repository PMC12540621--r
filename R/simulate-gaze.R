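#' Ex-Gaussian random deviates
#'
#' Sum of a normal and an independent exponential deviate — the standard
#' generative family for saccadic and manual reaction times (right-skewed,
#' with `tau` controlling the exponential tail).
#'
#' @param n Number of draws.
#' @param mu,sigma Mean and SD of the Gaussian component (ms).
#' @param tau Mean of the exponential component (ms).
#' @return Numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

condition_shift <- function(profile, age_months, condition) {
  switch(condition,
         gap = 0,
         overlap = profile_gap_effect(profile, age_months),
         baseline = profile_facilitation(profile, age_months),
         stop("unknown condition: ", condition))
}

#' Simulate the gaze-sample stream of one Gap-Overlap trial
#'
#' Generates per-eye gaze samples at the task's sampling rate from trial
#' start to the end of the response window. Before the saccade, both eyes sit
#' at screen center (0, 0) plus isotropic Gaussian noise with per-axis SD
#' `noise_rms_deg / 2`, calibrated so the two-axis RMS sample-to-sample
#' precision statistic equals `noise_rms_deg` in expectation. The saccade
#' latency is drawn from the participant's ex-Gaussian at this age, plus the
#' gap-effect shift in the overlap condition or the facilitation shift in the
#' baseline condition. At `peripheral_onset + latency` the gaze moves over a
#' 2-sample ramp to the peripheral target (`+/- eccentricity`, 0) plus a 1
#' degree SD landing error, and stays there. Each sample of each eye is
#' independently invalidated with probability `data_loss_prob` (positions set
#' to `NA`).
#'
#' Contaminant trials override the clean process: `premature` draws a latency
#' below 150 ms, `wrong_dir` lands on the opposite side, `no_move` never
#' leaves center. The label is returned as hidden ground truth and must not
#' be consumed by preprocessing.
#'
#' @param schedule One row of a [schedule_session()] schedule (data.frame or
#'   list with `trial_id`, `condition`, `side`, `peripheral_onset_ms`).
#' @param profile A [latent_profile()].
#' @param age_months Participant age at this session.
#' @param task A [task_spec()].
#' @param seed Optional integer seed.
#' @param force_latency_ms Override the drawn latency (testing hook).
#' @param force_contaminant One of `"none"`, `"premature"`, `"wrong_dir"`,
#'   `"no_move"` to force the contaminant draw, or `NULL` to draw it.
#' @return A list of class `trial_sim`: `gaze` (data.frame with `trial_id`,
#'   `t_ms`, `lx_deg`, `ly_deg`, `rx_deg`, `ry_deg`, `l_valid`, `r_valid`),
#'   `true_latency_ms` (`NA` for no-movement trials), and `contaminant`.
#' @export
simulate_trial_gaze <- function(schedule, profile, age_months,
                                task = task_spec(), seed = NULL,
                                force_latency_ms = NULL,
                                force_contaminant = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(schedule)) {
    stopifnot(nrow(schedule) == 1L)
    schedule <- as.list(schedule)
  }
  dt <- 1000 / task$sampling_rate_hz
  p_on <- schedule$peripheral_onset_ms
  t_end <- p_on + task$peripheral_timeout_ms
  t_ms <- seq(0, t_end, by = dt)
  n <- length(t_ms)

  contaminant <- force_contaminant
  if (is.null(contaminant)) {
    u <- stats::runif(1)
    cum <- cumsum(c(profile$premature_prob, profile$wrong_dir_prob,
                    profile$no_move_prob))
    contaminant <- if (u < cum[1]) "premature"
      else if (u < cum[2]) "wrong_dir"
      else if (u < cum[3]) "no_move"
      else "none"
  }

  latency <- force_latency_ms
  if (is.null(latency)) {
    latency <- if (contaminant == "premature") {
      stats::runif(1, 30, 149)
    } else {
      rexgauss(1, profile_mu(profile, age_months), profile$sigma_ms,
               profile$tau_ms) +
        condition_shift(profile, age_months, schedule$condition)
    }
  }
  if (contaminant == "no_move") latency <- NA_real_

  side_sign <- if (schedule$side == "left") -1 else 1
  if (contaminant == "wrong_dir") side_sign <- -side_sign
  target_x <- side_sign * task$peripheral_eccentricity_deg
  land <- stats::rnorm(2, 0, 1)  # shared landing error, x and y

  # noiseless trajectory common to both eyes
  x0 <- rep(0, n)
  y0 <- rep(0, n)
  if (!is.na(latency) && is.finite(latency)) {
    onset <- p_on + latency
    if (onset < t_end) {
      ramp <- t_ms >= onset & t_ms < onset + 2 * dt
      after <- t_ms >= onset + 2 * dt
      frac <- (t_ms[ramp] - onset) / (2 * dt)
      x0[ramp] <- frac * (target_x + land[1])
      y0[ramp] <- frac * land[2]
      x0[after] <- target_x + land[1]
      y0[after] <- land[2]
    }
  }

  s <- profile$noise_rms_deg / 2
  mk_eye <- function() {
    valid <- stats::runif(n) >= profile$data_loss_prob
    x <- x0 + stats::rnorm(n, 0, s)
    y <- y0 + stats::rnorm(n, 0, s)
    x[!valid] <- NA_real_
    y[!valid] <- NA_real_
    list(x = x, y = y, valid = valid)
  }
  le <- mk_eye()
  re <- mk_eye()

  gaze <- data.frame(
    trial_id = schedule$trial_id,
    t_ms = t_ms,
    lx_deg = le$x, ly_deg = le$y,
    rx_deg = re$x, ry_deg = re$y,
    l_valid = le$valid, r_valid = re$valid,
    stringsAsFactors = FALSE
  )
  structure(list(gaze = gaze,
                 true_latency_ms = latency,
                 contaminant = contaminant),
            class = "trial_sim")
}

#' Simulate all trials of one session
#'
#' Convenience wrapper around [simulate_trial_gaze()] for a full schedule.
#'
#' @param schedule A [schedule_session()] schedule.
#' @param profile,age_months,task,seed As in [simulate_trial_gaze()].
#' @return A list with `gaze` (named list of per-trial gaze data.frames) and
#'   `truth` (data.frame: `trial_id`, `condition`, `side`,
#'   `true_latency_ms`, `contaminant`).
#' @export
simulate_session_gaze <- function(schedule, profile, age_months,
                                  task = task_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(seq_len(nrow(schedule)), function(i) {
    simulate_trial_gaze(schedule[i, ], profile, age_months, task)
  })
  truth <- data.frame(
    trial_id = schedule$trial_id,
    condition = schedule$condition,
    side = schedule$side,
    true_latency_ms = vapply(sims, `[[`, numeric(1), "true_latency_ms"),
    contaminant = vapply(sims, `[[`, character(1), "contaminant"),
    stringsAsFactors = FALSE
  )
  gaze <- lapply(sims, `[[`, "gaze")
  names(gaze) <- schedule$trial_id
  list(gaze = gaze, truth = truth)
}

#' Latency-level simulation of per-participant summary effects
#'
#' Draws trial SRTs directly from each measurement's ex-Gaussian latency
#' model (no gaze samples) and computes the per-participant, per-condition
#' median SRTs and the derived gap and facilitation effects. This is the
#' fast path for large-cohort statistical simulation; the gaze-level path
#' ([simulate_session_gaze()] plus the preprocessing module) exercises the
#' full pipeline on the same latent model.
#'
#' @param cohort A [build_cohort()] table.
#' @param trials_per_condition Valid trials contributing to each median
#'   (default 16, a full standard session with no losses).
#' @param seed Optional integer seed.
#' @return The cohort table (minus the `profile` list-column) with added
#'   columns `median_gap_ms`, `median_overlap_ms`, `median_baseline_ms`,
#'   `gap_effect_ms`, `facilitation_ms`.
#' @export
simulate_participant_effects <- function(cohort, trials_per_condition = 16,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  k <- trials_per_condition
  med_draw <- function(mu, sigma, tau, shift) {
    if (n == 0L) return(numeric(0))
    # k draws per measurement row (column-major), column-wise medians
    draws <- rexgauss(n * k, rep(mu, each = k), rep(sigma, each = k),
                      rep(tau, each = k)) + rep(shift, each = k)
    apply(matrix(draws, nrow = k), 2, stats::median)
  }
  mu <- cohort$true_mu_ms
  sigma <- vapply(cohort$profile, `[[`, numeric(1), "sigma_ms")
  tau <- vapply(cohort$profile, `[[`, numeric(1), "tau_ms")
  med_gap <- med_draw(mu, sigma, tau, rep(0, n))
  med_ov <- med_draw(mu, sigma, tau, cohort$true_gap_effect_ms)
  med_ba <- med_draw(mu, sigma, tau, cohort$true_facilitation_ms)
  out <- cohort[setdiff(names(cohort), "profile")]
  out$median_gap_ms <- med_gap
  out$median_overlap_ms <- med_ov
  out$median_baseline_ms <- med_ba
  out$gap_effect_ms <- med_ov - med_gap
  out$facilitation_ms <- med_ba - med_gap
  out
}
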
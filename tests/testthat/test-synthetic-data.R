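test_that("cohort ages respect wave bounds and empty cohorts are allowed", {
  spec <- cohort_spec(n_per_wave = c(200, 0, 0, 0, 0, 0), seed = 11)
  coh <- build_cohort(spec)
  expect_equal(nrow(coh), 200)
  expect_true(all(coh$age_months >= 3 & coh$age_months <= 8))

  empty <- build_cohort(cohort_spec(n_per_wave = rep(0L, 6), seed = 1))
  expect_equal(nrow(empty), 0)
})

test_that("retention produces the expected within-person overlap", {
  waves2 <- default_waves()[1:2, ]
  spec <- cohort_spec(waves = waves2, n_per_wave = c(1000, 1000),
                      retention_prob = 0.5, seed = 12)
  coh <- build_cohort(spec)
  n_repeat <- sum(table(coh$participant_id) == 2)
  # binomial 99% interval around 500 at n = 1000, p = 0.5
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(n_repeat, bounds[1])
  expect_lte(n_repeat, bounds[2])
  # returning participants keep identifier and latent scales
  rep_ids <- names(which(table(coh$participant_id) == 2))
  one <- coh[coh$participant_id == rep_ids[1], ]
  expect_equal(one$gap_scale[1], one$gap_scale[2])
  # seed replay is bit-identical
  coh2 <- build_cohort(cohort_spec(waves = waves2, n_per_wave = c(1000, 1000),
                                   retention_prob = 0.5, seed = 12))
  expect_identical(coh$age_months, coh2$age_months)
  expect_identical(coh$participant_id, coh2$participant_id)
})

test_that("cohort_spec rejects invalid designs", {
  waves_bad <- default_waves()
  waves_bad$target_age_months <- rev(waves_bad$target_age_months)
  expect_error(cohort_spec(waves = waves_bad), "strictly increasing")
  expect_error(cohort_spec(n_per_wave = c(-1, 0, 0, 0, 0, 0)), ">= 0")
  expect_error(cohort_spec(retention_prob = 1.2), "\\[0, 1\\]")
})

test_that("a standard session has 48 balanced trials and the extra block makes 60", {
  s <- schedule_session(task_spec(), seed = 21)
  expect_equal(nrow(s), 48)
  expect_equal(as.vector(table(s$condition)), rep(16L, 3))
  side_by_cond <- table(s$condition, s$side)
  expect_true(all(side_by_cond == 8))

  s60 <- schedule_session(task_spec(), force_extra_block = TRUE, seed = 21)
  expect_equal(nrow(s60), 60)
  expect_equal(as.vector(table(s60$condition)), rep(20L, 3))
})

test_that("schedule timing honours the condition contracts", {
  task <- task_spec()
  s <- schedule_session(task, force_extra_block = TRUE, seed = 22)
  gap <- s$condition == "gap"
  base <- s$condition == "baseline"
  ov <- s$condition == "overlap"
  expect_equal(s$peripheral_onset_ms[gap] - s$center_offset_ms[gap],
               rep(200, sum(gap)))
  expect_equal(s$peripheral_onset_ms[base], s$center_offset_ms[base])
  expect_true(all(s$center_offset_ms[ov] >=
                    s$peripheral_onset_ms[ov] + task$peripheral_timeout_ms))
  isi <- s$peripheral_onset_ms - task$fixation_confirm_ms
  expect_true(all(isi >= 600 & isi <= 700))

  s_fix <- schedule_session(task_spec(isi_range_ms = c(600, 600)), seed = 23)
  expect_equal(s_fix$peripheral_onset_ms - task$fixation_confirm_ms,
               rep(600, 48))
})

test_that("trial counts not divisible by 3 are rejected", {
  expect_error(task_spec(trials_per_block = 10, n_blocks = 4), "divisible by 3")
})

test_that("zero-noise gaze sits exactly at center before the saccade", {
  task <- task_spec()
  sched <- make_schedule_row(peripheral_onset_ms = 1000)
  sim <- simulate_trial_gaze(sched, clean_profile(), 10, task, seed = 31,
                             force_latency_ms = 300, force_contaminant = "none")
  g <- sim$gaze
  pre <- g$t_ms < 1300
  expect_true(all(g$lx_deg[pre] == 0 & g$ly_deg[pre] == 0))
  expect_true(all(g$rx_deg[pre] == 0))
  # first sample away from center is at onset + latency, within 2 periods
  dt <- 1000 / task$sampling_rate_hz
  first_off <- min(g$t_ms[abs(g$lx_deg) > 1])
  expect_lte(abs(first_off - 1300), 2 * dt)
  # and the eye lands on the scheduled (right) side near the eccentricity
  expect_gt(mean(g$lx_deg[g$t_ms > 1500]), 10)
})

test_that("per-sample data loss matches its Bernoulli rate and is marked NA", {
  p <- latent_profile("P1", data_loss_prob = 0.5)
  sched <- make_schedule_row()
  set.seed(32)
  g <- simulate_trial_gaze(sched, p, 10, task_spec(),
                           force_contaminant = "none")$gaze
  n <- nrow(g)
  n_invalid <- sum(!g$l_valid) + sum(!g$r_valid)
  bounds <- qbinom(c(0.005, 0.995), 2 * n, 0.5)
  expect_gte(n_invalid, bounds[1])
  expect_lte(n_invalid, bounds[2])
  expect_true(all(is.na(g$lx_deg[!g$l_valid])))
  expect_true(all(!is.na(g$rx_deg[g$r_valid])))
})

test_that("latency shifts equal the gap and facilitation effects in expectation", {
  p <- clean_profile()
  age <- 12
  n <- 10000
  set.seed(33)
  gap_draws <- rexgauss(n, profile_mu(p, age), p$sigma_ms, p$tau_ms)
  ov_draws <- rexgauss(n, profile_mu(p, age), p$sigma_ms, p$tau_ms) +
    profile_gap_effect(p, age)
  se <- sqrt(var(gap_draws) / n + var(ov_draws) / n)
  expect_lt(abs(mean(ov_draws) - mean(gap_draws) - profile_gap_effect(p, age)),
            3 * se)
})

test_that("trial simulation is bit-identical under seed replay", {
  sched <- make_schedule_row()
  p <- latent_profile("P1")
  a <- simulate_trial_gaze(sched, p, 10, task_spec(), seed = 34)
  b <- simulate_trial_gaze(sched, p, 10, task_spec(), seed = 34)
  expect_identical(a$gaze, b$gaze)
  expect_identical(a$true_latency_ms, b$true_latency_ms)
  expect_identical(a$contaminant, b$contaminant)
})

test_that("contaminant draws honour their per-trial probabilities", {
  p <- latent_profile("P1", premature_prob = 0.3, wrong_dir_prob = 0.2,
                      no_move_prob = 0.1)
  sched <- make_schedule_row()
  set.seed(35)
  labels <- replicate(400, simulate_trial_gaze(sched, p, 10,
                                               task_spec())$contaminant)
  tab <- table(factor(labels, levels = c("premature", "wrong_dir",
                                         "no_move", "none")))
  for (lab_p in list(c("premature", 0.3), c("wrong_dir", 0.2),
                     c("no_move", 0.1), c("none", 0.4))) {
    pr <- as.numeric(lab_p[2])
    bounds <- qbinom(c(0.005, 0.995), 400, pr)
    expect_gte(tab[[lab_p[1]]], bounds[1])
    expect_lte(tab[[lab_p[1]]], bounds[2])
  }
})
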
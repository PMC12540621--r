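test_that("random-intercept model recovers a known slope across replicates", {
  hits <- 0L
  for (rep in 1:40) {
    set.seed(900 + rep)
    n <- 150
    intercepts <- rnorm(n, 300, 20)
    d <- data.frame(
      participant_id = rep(sprintf("p%03d", 1:n), 2),
      age_months = c(runif(n, 5, 20), runif(n, 30, 60)),
      value = NA_real_)
    d$value <- rep(intercepts, 2) - 2.0 * d$age_months + rnorm(2 * n, 0, 15)
    fit <- fit_random_intercept_model(d)
    if (fit$ci_low <= -2.0 && -2.0 <= fit$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.9)
})

test_that("mixed model degrades to OLS with singletons and flags constants", {
  set.seed(91)
  d <- data.frame(participant_id = sprintf("p%d", 1:50),
                  age_months = runif(50, 5, 100))
  d$value <- 100 - 0.8 * d$age_months + rnorm(50, 0, 10)
  expect_warning(fit <- fit_random_intercept_model(d), "ordinary least squares")
  ols <- unname(coef(lm(value ~ age_months, d))[2])
  expect_equal(fit$b, ols, tolerance = 1e-6)
  expect_equal(fit$method, "ols")

  # constant outcome with repeats: slope 0 (singular random effect signaled)
  d2 <- data.frame(participant_id = rep(sprintf("p%d", 1:20), 2),
                   age_months = runif(40, 5, 100), value = 7)
  fit2 <- suppressWarnings(fit_random_intercept_model(d2))
  expect_equal(fit2$b, 0, tolerance = 1e-8)
})

test_that("holm adjustment matches the hand-applied step-down", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.04, 0.01)), c(0.04, 0.02))
  # three values, hand computation: sorted (.005,.02,.03)*(3,2,1), monotone
  expect_equal(holm_adjust(c(0.02, 0.005, 0.03)), c(0.04, 0.015, 0.04))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(92)
  p <- runif(10)
  # dominated by Bonferroni elementwise
  expect_true(all(holm_adjust(p) <= pmin(p * length(p), 1) + 1e-12))
  # invariant under permutation (up to reordering)
  perm <- sample(10)
  expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
  # p_holm >= p_raw always
  expect_true(all(holm_adjust(p) >= p))
})

test_that("paired comparisons produce closed-form effect sizes", {
  set.seed(93)
  n <- 30
  base <- rnorm(n, 500, 40)
  wide <- data.frame(w1 = base + 50 + rnorm(n, 0, 10), w2 = base)
  res <- paired_condition_comparisons(wide, method_rule = "t")
  expect_equal(nrow(res), 1)
  d_expected <- mean(wide$w1 - wide$w2) / sd(wide$w1 - wide$w2)
  expect_equal(res$effect_size, d_expected, tolerance = 1e-12)
  expect_gt(res$effect_size, 3.5)  # shift 50, sd 10 -> d near 5

  # identical samples: degenerate, effect 0, maximal p
  same <- data.frame(w1 = base, w2 = base)
  res0 <- suppressWarnings(paired_condition_comparisons(same))
  expect_equal(res0$effect_size, 0)
  expect_equal(res0$p_raw, 1)

  # wilcoxon branch: rank-biserial bounded, sign follows the shift
  res_w <- paired_condition_comparisons(wide, method_rule = "wilcoxon")
  expect_lte(abs(res_w$effect_size), 1)
  expect_gt(res_w$effect_size, 0.9)
  expect_equal(res_w$test, "wilcoxon")
})

test_that("holm correction spans the whole contrast family", {
  set.seed(94)
  n <- 25
  base <- rnorm(n, 500, 30)
  wide <- data.frame(w1 = base + 60 + rnorm(n, 0, 15),
                     w2 = base + 30 + rnorm(n, 0, 15),
                     w3 = base)
  res <- paired_condition_comparisons(wide, method_rule = "t")
  expect_equal(nrow(res), 3)
  expect_equal(res$p_holm, holm_adjust(res$p_raw))
  expect_true(all(res$p_holm >= res$p_raw))
})

test_that("cross-wave correlations capture stability and respect null bounds", {
  # perfectly stable measure: every defined cell r = 1
  ids <- sprintf("p%03d", 1:40)
  stable <- do.call(rbind, lapply(c("w1", "w2", "w3"), function(w) {
    data.frame(participant_id = ids, wave_label = w,
               gap_effect_ms = seq(10, 400, length.out = 40))
  }))
  cw <- cross_wave_correlation_matrix(stable, waves = c("w1", "w2", "w3"))
  expect_equal(cw$r[upper.tri(cw$r)], rep(1, 3))
  expect_equal(cw$n[1, 2], 40)
  expect_true(all(is.na(cw$r[lower.tri(cw$r, diag = TRUE)])))

  # independent values: |r| below the 99% null bound at n = 500
  set.seed(95)
  indep <- do.call(rbind, lapply(c("w1", "w2"), function(w) {
    data.frame(participant_id = sprintf("p%03d", 1:500), wave_label = w,
               gap_effect_ms = rnorm(500))
  }))
  cw2 <- cross_wave_correlation_matrix(indep, waves = c("w1", "w2"))
  expect_lt(abs(cw2$r[1, 2]), 2.58 / sqrt(500 - 1))

  # cells without overlap stay absent
  sparse <- rbind(
    data.frame(participant_id = c("a", "b", "c"), wave_label = "w1",
               gap_effect_ms = 1:3),
    data.frame(participant_id = c("x", "y", "z"), wave_label = "w2",
               gap_effect_ms = 4:6))
  cw3 <- cross_wave_correlation_matrix(sparse, waves = c("w1", "w2"))
  expect_true(is.na(cw3$r[1, 2]))
  expect_equal(cw3$n[1, 2], 0)
})

test_that("two-wave omnibus equals the squared paired t", {
  set.seed(96)
  n <- 35
  base <- rnorm(n, 400, 50)
  d <- data.frame(participant_id = rep(sprintf("p%d", 1:n), 2),
                  wave_label = rep(c("w1", "w2"), each = n),
                  value = c(base + 40 + rnorm(n, 0, 25), base))
  om <- run_omnibus(d, waves = c("w1", "w2"))
  tt <- t.test(d$value[d$wave_label == "w1"], d$value[d$wave_label == "w2"],
               paired = TRUE)
  expect_equal(om$F, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(om$p, tt$p.value, tolerance = 1e-6)
  expect_gte(om$F, 0)
  expect_true(om$eta_sq_partial >= 0 && om$eta_sq_partial <= 1)
})

test_that("identical columns give a near-zero omnibus effect", {
  set.seed(97)
  vals <- rnorm(20, 100, 10)
  d <- data.frame(participant_id = rep(sprintf("p%d", 1:20), 3),
                  wave_label = rep(c("w1", "w2", "w3"), each = 20),
                  value = rep(vals, 3) + rnorm(60, 0, 1e-6))
  om <- run_omnibus(d, waves = c("w1", "w2", "w3"))
  expect_lt(om$eta_sq_partial, 0.2)
  expect_error(run_omnibus(d[d$wave_label == "w1", ]), "at least 2 waves")
})

test_that("the omnibus detects a d = 1 wave effect with high power", {
  detections <- 0L
  for (rep in 1:60) {
    set.seed(980 + rep)
    n <- 60
    subj <- rnorm(n, 0, 30)
    d <- data.frame(participant_id = rep(sprintf("p%d", 1:n), 2),
                    wave_label = rep(c("w1", "w2"), each = n),
                    value = c(subj + 28.3 + rnorm(n, 0, 20), subj + rnorm(n, 0, 20)))
    if (run_omnibus(d, waves = c("w1", "w2"))$p < 0.05) {
      detections <- detections + 1L
    }
  }
  expect_gte(detections / 60, 0.95)
})
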
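demo_def <- function() {
  subscale_definition("ECBQ", "demo", c("a", "b", "c"), "b",
                      "likert_1_7", "mean")
}

test_that("subscale scoring applies reverse coding before aggregation", {
  resp <- data.frame(item_id = c("a", "b", "c"), response = c(1, 7, 4))
  expect_equal(score_subscale(resp, demo_def()), 2.0)  # mean of 1, 1, 4

  const <- data.frame(item_id = c("a", "b", "c"), response = c(4, 4, 4))
  expect_equal(score_subscale(const, demo_def()), 4.0)

  cbcl <- subscale_definition("CBCL", "sum0", c("i1", "i2", "i3"),
                              scale = "three_point_0_2", aggregation = "sum")
  zeros <- data.frame(item_id = c("i1", "i2", "i3"), response = c(0, 0, 0))
  expect_equal(score_subscale(zeros, cbcl), 0)
})

test_that("missing or off-scale items reject the subscale", {
  expect_error(score_subscale(
    data.frame(item_id = c("a", "b"), response = c(1, 2)), demo_def()),
    "missing item")
  expect_error(score_subscale(
    data.frame(item_id = c("a", "b", "c"), response = c(0, 2, 3)), demo_def()),
    "off-scale")
  expect_error(subscale_definition("ECBQ", "bad", c("a"), "z"), "subset")
  expect_error(subscale_definition("ECBQ", "bad", character(0)), "non-empty")
})

test_that("reverse coding is an involution on random response tables", {
  set.seed(101)
  for (rep in 1:20) {
    v <- sample(1:7, 8, replace = TRUE)
    expect_equal(8 - (8 - v), v, ignore_attr = TRUE)
    # and scoring a fully reversed subscale of reversed responses matches
    def_fwd <- subscale_definition("ECBQ", "s", sprintf("i%d", 1:8),
                                   character(0))
    def_rev <- subscale_definition("ECBQ", "s", sprintf("i%d", 1:8),
                                   sprintf("i%d", 1:8))
    resp_fwd <- data.frame(item_id = sprintf("i%d", 1:8), response = v)
    resp_rev <- data.frame(item_id = sprintf("i%d", 1:8), response = 8 - v)
    expect_equal(score_subscale(resp_rev, def_rev),
                 score_subscale(resp_fwd, def_fwd))
  }
})

test_that("scoring bounds hold on simulated data", {
  coh <- data.frame(participant_id = sprintf("P%03d", 1:60),
                    age_months = runif(60, 20, 150),
                    true_gap_effect_ms = rexp(60, 1 / 60))
  resp <- simulate_questionnaires(coh, rho = 0.3, seed = 102)
  scores <- score_questionnaires(resp)
  lik <- scores[scores$instrument != "CBCL", ]
  expect_true(all(lik$raw_score >= 1 & lik$raw_score <= 7))
  cbcl <- scores[scores$instrument == "CBCL", ]
  expect_true(all(cbcl$raw_score >= 0 & cbcl$raw_score <= 2 * 7))
})

test_that("T conversion is linear in the norm and validates its inputs", {
  expect_equal(to_t_score(10, c(10, 2)), 50)
  expect_equal(to_t_score(12, c(10, 2)), 60)
  expect_equal(to_t_score(7, c(10, 2)), 35)
  expect_error(to_t_score(5, c(10, 0)), "sd must be > 0")
  # lookup-table norms: exact match, domain errors signaled
  tab <- data.frame(raw = 0:5, t = c(50, 55, 60, 65, 70, 80))
  expect_equal(to_t_score(c(0, 4), tab), c(50, 70))
  expect_error(to_t_score(9, tab), "domain")
})

test_that("clinical classification partitions T-scores at 64/65 and 69/70", {
  expect_equal(classify_clinical_range(c(64, 67, 71)),
               c("healthy", "borderline", "clinical"))
  expect_equal(classify_clinical_range(65), "borderline")
  expect_equal(classify_clinical_range(69), "borderline")
  expect_equal(classify_clinical_range(70), "clinical")
  # every finite T falls in exactly one range
  t_grid <- seq(20, 100, by = 0.5)
  cls <- classify_clinical_range(t_grid)
  expect_true(all(cls %in% c("healthy", "borderline", "clinical")))
})

test_that("trait-gap correlations are recovered per age group", {
  set.seed(103)
  n <- 1000
  coh <- data.frame(participant_id = sprintf("P%04d", 1:n),
                    wave_label = "6y",
                    age_months = runif(n, 72, 90),
                    true_gap_effect_ms = rexp(n, 1 / 60) + 20)
  rho <- 0.4
  resp <- simulate_questionnaires(coh, rho = rho, seed = 104)
  scores <- score_questionnaires(resp, norms = synthetic_norms())
  summaries <- data.frame(participant_id = coh$participant_id,
                          wave_label = "6y",
                          gap_effect_ms = coh$true_gap_effect_ms)
  res <- correlate_with_gap_effect(scores, summaries)
  cell <- res[res$subscale == "cbcl_adhd" & res$measure == "gap_effect_ms", ]
  expect_equal(cell$n, n)
  # attenuation: the observed item-sum correlation is below the latent rho
  expect_gt(cell$r, 0.15)
  expect_lt(cell$r, rho + 0.06)

  # degenerate cells are absent, not errors
  tiny <- summaries[1:2, ]
  res2 <- correlate_with_gap_effect(scores, tiny)
  expect_true(all(is.na(res2$r)))
  expect_true(all(res2$n <= 2))
})

test_that("subscale definitions round-trip through YAML", {
  defs <- default_subscale_definitions()
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(defs, unclass), path)
  back <- read_subscale_definitions(path)
  expect_equal(names(back), names(defs))
  expect_equal(back$cbcl_adhd$item_ids, defs$cbcl_adhd$item_ids)
  expect_equal(back$ecbq_attentional_shifting$reverse_coded_ids,
               defs$ecbq_attentional_shifting$reverse_coded_ids)
})
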
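#' Synthetic linear norms for the shipped subscale definitions
#'
#' Linear `(mean, sd)` norms matched to the synthetic item generator's
#' marginal distributions, for testing T-score conversion. They are
#' synthetic stand-ins: real normative tables are publisher-supplied and
#' must be provided by the user for real data.
#'
#' @return Named list of `c(mean, sd)` per default subscale key.
#' @export
synthetic_norms <- function() {
  list(ecbq_attentional_shifting = c(4, 0.8),
       ecbq_attentional_focusing = c(4, 0.8),
       cbq_attentional_focusing = c(4, 0.8),
       cbcl_adhd = c(2.8, 2.2))
}

#' Run configuration for the simulate/preprocess/analyze pipeline
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed; every stage derives its RNG stream from
#'   it, making the whole run reproducible.
#' @param scenario Path to a YAML scenario file, or a named list with
#'   optional blocks `task`, `cohort` (`n_per_wave`, `retention_prob`),
#'   `profile` (latent-profile arguments), `questionnaire` (`rho`), or
#'   `NULL` for package defaults at a small demonstration size.
#' @param stages Character vector of stages to run, in pipeline order, from
#'   `"simulate"`, `"preprocess"`, `"analyze"`, `"score_questionnaires"`,
#'   `"report"`.
#' @param n_iter Bootstrap iterations for the analyze stage.
#' @param thresholds A [filter_thresholds()] (override of rms/loss/RT
#'   bounds).
#' @param min_trials Minimum retained trials per condition.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, scenario = NULL,
                       stages = c("simulate", "preprocess", "analyze",
                                  "score_questionnaires", "report"),
                       n_iter = 1000,
                       thresholds = filter_thresholds(),
                       min_trials = 4) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (n_iter < 1) stop("run_config: n_iter must be >= 1")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("run_config: seed must be an integer")
  structure(list(out_dir = out_dir, seed = seed, scenario = scenario,
                 stages = stages, n_iter = n_iter, thresholds = thresholds,
                 min_trials = min_trials),
            class = "run_config")
}

load_scenario <- function(scenario) {
  sc <- if (is.null(scenario)) {
    list()
  } else if (is.character(scenario)) {
    yaml::read_yaml(scenario)
  } else {
    scenario
  }
  task <- do.call(task_spec, sc$task %||% list())
  cohort_args <- sc$cohort %||% list(n_per_wave = c(12, 12, 8, 6, 8, 6),
                                     retention_prob = c(0.6, 0.5, 0.3, 0, 0.3))
  profile_args <- sc$profile %||% list()
  rho <- (sc$questionnaire %||% list(rho = 0.3))$rho %||% 0.3
  list(task = task, cohort_args = cohort_args, profile_args = profile_args,
       rho = rho)
}

#' Run the pipeline
#'
#' Executes the enabled stages in order against the output directory:
#' `simulate` writes the cohort table, per-measurement trial schedules and
#' gaze-sample files, and questionnaire responses; `preprocess` reads them
#' back and writes per-trial results, quality metrics, participant
#' summaries, and the exclusion audit; `analyze` writes bootstrap
#' age-correlation results (observed and shuffled null), the mixed-model
#' fits, and the cross-wave correlation matrix; `score_questionnaires`
#' writes subscale scores and their correlations with the gap effect;
#' `report` writes a JSON run manifest (seed, config hash, package version,
#' stage outputs). Stage preconditions are checked before anything is
#' written; re-running a downstream stage alone reproduces its outputs from
#' the upstream files.
#'
#' @param config A [run_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc <- load_scenario(config$scenario)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  gaze_dir <- file.path(out, "gaze")
  paths <- list(
    cohort = file.path(out, "cohort.csv"),
    schedules = file.path(out, "schedules.csv"),
    responses = file.path(out, "questionnaire_responses.csv"),
    trial_results = file.path(out, "trial_results.csv"),
    qc = file.path(out, "trial_qc.csv"),
    summaries = file.path(out, "participant_summaries.csv"),
    audit = file.path(out, "filter_audit.csv"),
    bootstrap = file.path(out, "bootstrap_correlations.csv"),
    lmm = file.path(out, "mixed_models.csv"),
    crosswave = file.path(out, "cross_wave_correlations.csv"),
    scores = file.path(out, "questionnaire_scores.csv"),
    qcorr = file.path(out, "questionnaire_correlations.csv"),
    manifest = file.path(out, "manifest.json")
  )
  written <- character(0)
  wcsv <- function(d, p) {
    data.table::fwrite(d, p)
    written <<- c(written, p)
  }

  if ("simulate" %in% config$stages) {
    spec <- do.call(cohort_spec, c(sc$cohort_args, list(seed = config$seed)))
    cohort <- build_cohort(spec, profile_args = sc$profile_args)
    dir.create(gaze_dir, showWarnings = FALSE)
    set.seed(config$seed + 1L)
    scheds <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      sched <- schedule_session(sc$task)
      sim <- simulate_session_gaze(sched, cohort$profile[[i]],
                                   cohort$age_months[i], sc$task)
      key <- paste0(cohort$participant_id[i], "_", cohort$wave_label[i])
      write_gaze_tsv(sim$gaze, file.path(gaze_dir, paste0(key, ".tsv")))
      sched$measurement <- key
      scheds[[i]] <- sched
    }
    wcsv(do.call(rbind, scheds), paths$schedules)
    wcsv(cohort[setdiff(names(cohort), "profile")], paths$cohort)
    resp <- simulate_questionnaires(cohort, rho = sc$rho,
                                    seed = config$seed + 2L)
    wcsv(resp, paths$responses)
  }

  if ("preprocess" %in% config$stages) {
    if (!file.exists(paths$schedules) || !dir.exists(gaze_dir)) {
      stop("preprocess stage: no schedules/gaze files in ", out,
           "; run the simulate stage first")
    }
    scheds <- data.table::fread(paths$schedules, data.table = FALSE)
    cohort <- data.table::fread(paths$cohort, data.table = FALSE)
    results <- list(); qcs <- list(); summaries <- list(); audits <- list()
    for (i in seq_len(nrow(cohort))) {
      key <- paste0(cohort$participant_id[i], "_", cohort$wave_label[i])
      gfile <- file.path(gaze_dir, paste0(key, ".tsv"))
      if (!file.exists(gfile)) stop("preprocess stage: missing gaze file ", gfile)
      gaze <- read_gaze_tsv(gfile)
      sched <- scheds[scheds$measurement == key, ]
      pp <- preprocess_session(gaze, sched, sc$task,
                               thresholds = config$thresholds)
      pp$results$measurement <- key
      pp$qc$measurement <- key
      results[[i]] <- pp$results
      qcs[[i]] <- pp$qc
      ok <- pp$results[pp$results$status == "ok", ]
      summaries[[i]] <- summarize_participant(
        ok, config$min_trials, cohort$participant_id[i],
        cohort$wave_label[i], cohort$age_months[i])
      audits[[i]] <- cbind(wave_label = cohort$wave_label[i],
                           filter_audit(pp$results))
    }
    results <- do.call(rbind, results)
    audit <- stats::aggregate(n ~ wave_label + status,
                              data = do.call(rbind, audits), FUN = sum)
    wcsv(results, paths$trial_results)
    wcsv(do.call(rbind, qcs), paths$qc)
    wcsv(do.call(rbind, summaries), paths$summaries)
    wcsv(audit, paths$audit)
  }

  if ("analyze" %in% config$stages) {
    if (!file.exists(paths$summaries)) {
      stop("analyze stage: no participant summaries in ", out,
           "; run the preprocess stage first")
    }
    summaries <- data.table::fread(paths$summaries, data.table = FALSE)
    boot_rows <- list()
    lmm_rows <- list()
    for (measure in c("gap_effect_ms", "facilitation_ms", "median_baseline_ms",
                      "median_gap_ms", "median_overlap_ms")) {
      d <- summaries[!is.na(summaries[[measure]]), ]
      if (length(unique(d$participant_id)) < 3) next
      obs <- bootstrap_age_correlation(d, measure, config$n_iter,
                                       seed = config$seed + 10L)
      nul <- shuffled_null_correlation(d, measure, config$n_iter,
                                       seed = config$seed + 11L)
      obs <- compare_to_null(obs, nul)
      boot_rows[[measure]] <- data.frame(
        measure = measure,
        median_r = obs$median_r, ci_low = obs$ci_low, ci_high = obs$ci_high,
        empirical_p = obs$empirical_p, rank_sum_p = obs$rank_sum_p,
        null_median_r = nul$median_r, null_ci_low = nul$ci_low,
        null_ci_high = nul$ci_high,
        n_iterations = obs$n_iterations, n = obs$n,
        stringsAsFactors = FALSE)
      if (measure %in% c("gap_effect_ms", "facilitation_ms")) {
        fit <- tryCatch(
          suppressWarnings(fit_random_intercept_model(d, measure)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          lmm_rows[[measure]] <- data.frame(
            measure = measure, b = fit$b, se = fit$se, z = fit$z,
            ci_low = fit$ci_low, ci_high = fit$ci_high, p = fit$p,
            random_intercept_variance = fit$random_intercept_variance,
            method = fit$method, stringsAsFactors = FALSE)
        }
      }
    }
    wcsv(do.call(rbind, boot_rows), paths$bootstrap)
    if (length(lmm_rows)) wcsv(do.call(rbind, lmm_rows), paths$lmm)
    cw <- cross_wave_correlation_matrix(summaries,
                                        waves = unique(summaries$wave_label))
    k <- nrow(cw$r)
    idx <- which(upper.tri(cw$r), arr.ind = TRUE)
    wcsv(data.frame(wave_a = rownames(cw$r)[idx[, 1]],
                    wave_b = colnames(cw$r)[idx[, 2]],
                    r = cw$r[idx], p = cw$p[idx], n = cw$n[idx]),
         paths$crosswave)
  }

  if ("score_questionnaires" %in% config$stages) {
    if (!file.exists(paths$responses) || !file.exists(paths$summaries)) {
      stop("score_questionnaires stage: needs questionnaire responses and ",
           "participant summaries; run earlier stages first")
    }
    resp <- data.table::fread(paths$responses, data.table = FALSE)
    summaries <- data.table::fread(paths$summaries, data.table = FALSE)
    scores <- score_questionnaires(resp, norms = synthetic_norms())
    wcsv(scores, paths$scores)
    wcsv(correlate_with_gap_effect(scores, summaries), paths$qcorr)
  }

  manifest <- list(
    package = "gapoverlap",
    version = as.character(utils::packageVersion("gapoverlap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_iter = config$n_iter,
    stages = config$stages,
    thresholds = unclass(config$thresholds),
    config_hash = config_hash(config),
    outputs = written
  )
  if ("report" %in% config$stages) {
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(manifest)
}

config_hash <- function(config) {
  key <- utils::capture.output(utils::str(
    config[c("seed", "scenario", "stages", "n_iter", "thresholds",
             "min_trials")]))
  # small stable polynomial hash over the printed config
  bytes <- utf8ToInt(paste(key, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}
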
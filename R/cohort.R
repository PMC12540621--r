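#' Default wave table for an accelerated longitudinal Gap-Overlap cohort
#'
#' Six measurement waves spanning infancy to early adolescence. Target ages,
#' age SDs, and age bounds (all in months) follow the published cohort
#' structure: waves near 5 and 10 months, 3, 6, 9 and 12 years, each jittered
#' around its target. The first four waves form the younger ("baby") cohort
#' and the last two the older ("teenage") cohort; retention across the 6-year
#' to 9-year boundary is zero because the two cohorts enrolled independently.
#'
#' @return A data.frame with columns `label`, `target_age_months`,
#'   `age_sd_months`, `age_lo_months`, `age_hi_months`, `cohort`.
#' @export
default_waves <- function() {
  data.frame(
    label = c("5mo", "10mo", "3y", "6y", "9y", "12y"),
    target_age_months = c(5.42, 10.48, 43.32, 73.62, 113.4, 158.15),
    age_sd_months = c(0.84, 1.10, 9.88, 6.63, 10.25, 13.01),
    age_lo_months = c(3, 8, 23, 60, 95, 133),
    age_hi_months = c(8, 18, 60, 91, 132, 187),
    cohort = c("baby", "baby", "baby", "baby", "teen", "teen"),
    stringsAsFactors = FALSE
  )
}

#' Cohort specification for the synthetic-data generator
#'
#' Defines the accelerated longitudinal design: the wave table (target ages,
#' jitter, bounds), how many datasets are collected per wave, and the
#' probability that a participant measured at wave *w* returns at wave
#' *w + 1*. Returning participants keep their identifier and latent profile;
#' remaining slots are filled with newly enrolled participants. Default
#' per-wave counts and retention probabilities emulate the published cohort's
#' sample sizes and within-person overlap (about 6700 datasets from about
#' 3300 unique children).
#'
#' @param waves Wave table as produced by [default_waves()].
#' @param n_per_wave Integer vector, datasets collected per wave.
#' @param retention_prob Probability of returning at the next wave; length 1
#'   or `nrow(waves) - 1`.
#' @param seed Integer seed making [build_cohort()] fully deterministic, or
#'   `NULL` to use the current RNG state.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(waves = default_waves(),
                        n_per_wave = c(1900, 1809, 1009, 336, 1269, 382),
                        retention_prob = c(0.85, 0.65, 0.30, 0.00, 0.28),
                        seed = NULL) {
  stopifnot(is.data.frame(waves),
            all(c("label", "target_age_months", "age_sd_months",
                  "age_lo_months", "age_hi_months") %in% names(waves)))
  n_per_wave <- as.integer(n_per_wave)
  if (length(n_per_wave) != nrow(waves)) {
    stop("cohort_spec: n_per_wave must have one entry per wave")
  }
  if (any(n_per_wave < 0L)) stop("cohort_spec: n_per_wave must be >= 0")
  if (nrow(waves) > 1 && any(diff(waves$target_age_months) <= 0)) {
    stop("cohort_spec: wave target ages must be strictly increasing")
  }
  n_trans <- max(nrow(waves) - 1L, 0L)
  if (length(retention_prob) == 1L) retention_prob <- rep(retention_prob, n_trans)
  if (length(retention_prob) != n_trans) {
    stop("cohort_spec: retention_prob must have length 1 or n_waves - 1")
  }
  if (any(retention_prob < 0 | retention_prob > 1)) {
    stop("cohort_spec: retention_prob must be in [0, 1]")
  }
  structure(list(waves = waves, n_per_wave = n_per_wave,
                 retention_prob = retention_prob, seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort specification:", nrow(x$waves), "waves,",
      sum(x$n_per_wave), "datasets\n")
  print(cbind(x$waves, n = x$n_per_wave))
  invisible(x)
}

#' Latent participant profile
#'
#' The generative model behind one participant's saccadic behaviour. Trial
#' SRTs in the gap condition follow an ex-Gaussian distribution whose
#' Gaussian mean declines with age; the overlap condition adds the
#' participant's gap effect (the disengagement cost) and the baseline
#' condition adds the facilitation effect (the anticipatory benefit), both
#' deterministic age-dependent shifts. Age trends are exponentials in age
#' (months): mean SRT `mu_scale * (250 + 400 exp(-age/24))` ms, gap effect
#' `gap_scale * (30 + 170 exp(-age/30))` ms, facilitation
#' `fac_scale * (10 + 60 exp(-age/30))` ms. The multiplicative `*_scale`
#' terms carry stable between-participant individual differences.
#'
#' @param participant_id Opaque identifier.
#' @param mu_scale,gap_scale,fac_scale Positive multipliers on the population
#'   age trends (1 = population average).
#' @param sigma_ms,tau_ms Ex-Gaussian sigma (Gaussian SD) and tau
#'   (exponential mean) in ms.
#' @param noise_rms_deg Target RMS sample-to-sample precision of the
#'   simulated gaze signal, degrees.
#' @param data_loss_prob Per-sample, per-eye probability of an invalid sample.
#' @param premature_prob,wrong_dir_prob,no_move_prob Per-trial contaminant
#'   probabilities (anticipatory saccade, saccade to the wrong side, no
#'   saccade at all).
#' @param trait_coupling_rho Latent correlation between the participant's gap
#'   effect and the questionnaire trait (informational default; the
#'   questionnaire generator takes its own `rho`).
#' @param trend Optional list overriding the age-trend constants
#'   (`mu_base`, `mu_amp`, `mu_tau`, `gap_base`, `gap_amp`, `gap_tau`,
#'   `fac_base`, `fac_amp`, `fac_tau`).
#' @return An object of class `latent_profile`.
#' @export
latent_profile <- function(participant_id,
                           mu_scale = 1, gap_scale = 1, fac_scale = 1,
                           sigma_ms = 50, tau_ms = 100,
                           noise_rms_deg = 0.5,
                           data_loss_prob = 0.15,
                           premature_prob = 0.05,
                           wrong_dir_prob = 0.05,
                           no_move_prob = 0.05,
                           trait_coupling_rho = 0,
                           trend = list()) {
  tr <- utils::modifyList(list(
    mu_base = 250, mu_amp = 400, mu_tau = 24,
    gap_base = 30, gap_amp = 170, gap_tau = 30,
    fac_base = 10, fac_amp = 60, fac_tau = 30
  ), trend)
  p <- list(participant_id = participant_id,
            mu_scale = mu_scale, gap_scale = gap_scale, fac_scale = fac_scale,
            sigma_ms = sigma_ms, tau_ms = tau_ms,
            noise_rms_deg = noise_rms_deg,
            data_loss_prob = data_loss_prob,
            premature_prob = premature_prob,
            wrong_dir_prob = wrong_dir_prob,
            no_move_prob = no_move_prob,
            trait_coupling_rho = trait_coupling_rho,
            trend = tr)
  class(p) <- "latent_profile"
  validate_latent_profile(p)
}

validate_latent_profile <- function(p) {
  stopifnot(inherits(p, "latent_profile"))
  if (p$sigma_ms <= 0 || p$tau_ms <= 0 || p$mu_scale <= 0) {
    stop("latent_profile: ex-Gaussian parameters must be positive")
  }
  probs <- c(p$data_loss_prob, p$premature_prob, p$wrong_dir_prob, p$no_move_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("latent_profile: probabilities must be in [0, 1]")
  }
  if (p$noise_rms_deg < 0) stop("latent_profile: noise_rms_deg must be >= 0")
  if (p$gap_scale < 0 || p$fac_scale < 0) {
    stop("latent_profile: effect scales must be >= 0")
  }
  p
}

#' Evaluate a latent profile's age trends
#'
#' `profile_mu` gives the ex-Gaussian mu (gap-condition Gaussian mean),
#' `profile_gap_effect` the expected overlap-minus-gap SRT difference, and
#' `profile_facilitation` the expected baseline-minus-gap difference, all in
#' ms at `age_months`.
#'
#' @param profile A [latent_profile()].
#' @param age_months Age in months (vectorised).
#' @return Numeric vector of ms.
#' @export
profile_mu <- function(profile, age_months) {
  tr <- profile$trend
  profile$mu_scale * (tr$mu_base + tr$mu_amp * exp(-age_months / tr$mu_tau))
}

#' @rdname profile_mu
#' @export
profile_gap_effect <- function(profile, age_months) {
  tr <- profile$trend
  profile$gap_scale * (tr$gap_base + tr$gap_amp * exp(-age_months / tr$gap_tau))
}

#' @rdname profile_mu
#' @export
profile_facilitation <- function(profile, age_months) {
  tr <- profile$trend
  profile$fac_scale * (tr$fac_base + tr$fac_amp * exp(-age_months / tr$fac_tau))
}

# inverse-CDF truncated normal draw on [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Build an accelerated longitudinal cohort
#'
#' Draws a cohort according to a [cohort_spec()]: ages come from each wave's
#' truncated normal within its bounds; a Bernoulli draw with the wave's
#' retention probability decides whether each participant returns at the next
#' wave (keeping identifier and latent profile, re-aged); remaining slots are
#' filled with new enrolments. Between-participant heterogeneity enters
#' through log-normal multipliers on the latent age trends.
#'
#' @param spec A [cohort_spec()].
#' @param profile_args Named list passed to [latent_profile()] for every
#'   participant (e.g. noise or contaminant levels).
#' @param scale_sd Named numeric: log-scale SDs of the individual multipliers
#'   (`mu`, `gap`, `fac`).
#' @return A data.frame with one row per participant-wave measurement:
#'   `participant_id`, `wave_label`, `wave_index`, `age_months`, the latent
#'   scalars `mu_scale`, `gap_scale`, `fac_scale`, the evaluated
#'   `true_mu_ms`, `true_gap_effect_ms`, `true_facilitation_ms`, and a
#'   `profile` list-column of [latent_profile()] objects.
#' @export
#' @examples
#' spec <- cohort_spec(n_per_wave = c(30, 30, 20, 10, 20, 10), seed = 1)
#' coh <- build_cohort(spec)
#' table(coh$wave_label)
build_cohort <- function(spec,
                         profile_args = list(),
                         scale_sd = c(mu = 0.15, gap = 0.30, fac = 0.30)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  waves <- spec$waves
  n_waves <- nrow(waves)

  profiles <- list()   # id -> latent_profile
  next_id <- 1L
  rows <- vector("list", n_waves)
  current_ids <- character(0)

  new_profile <- function(id) {
    args <- utils::modifyList(profile_args, list(
      participant_id = id,
      mu_scale = exp(stats::rnorm(1, 0, scale_sd[["mu"]])),
      gap_scale = exp(stats::rnorm(1, 0, scale_sd[["gap"]])),
      fac_scale = exp(stats::rnorm(1, 0, scale_sd[["fac"]]))
    ))
    do.call(latent_profile, args)
  }

  for (w in seq_len(n_waves)) {
    n_w <- spec$n_per_wave[w]
    # returning participants from the previous wave
    if (w > 1L && length(current_ids) > 0 && spec$retention_prob[w - 1L] > 0) {
      keep <- stats::runif(length(current_ids)) < spec$retention_prob[w - 1L]
      returning <- current_ids[keep]
    } else {
      returning <- character(0)
    }
    if (length(returning) > n_w) {
      returning <- sample(returning, n_w)
    }
    n_new <- n_w - length(returning)
    new_ids <- character(0)
    if (n_new > 0L) {
      new_ids <- sprintf("P%05d", seq.int(next_id, length.out = n_new))
      next_id <- next_id + n_new
      for (id in new_ids) profiles[[id]] <- new_profile(id)
    }
    ids_w <- c(returning, new_ids)
    if (length(ids_w) > 0L) {
      ages <- rtruncnorm(length(ids_w), waves$target_age_months[w],
                         waves$age_sd_months[w],
                         waves$age_lo_months[w], waves$age_hi_months[w])
      rows[[w]] <- data.frame(participant_id = ids_w,
                              wave_label = waves$label[w],
                              wave_index = w,
                              age_months = ages,
                              stringsAsFactors = FALSE)
    }
    current_ids <- ids_w
  }

  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(participant_id = character(0), wave_label = character(0),
                      wave_index = integer(0), age_months = numeric(0),
                      mu_scale = numeric(0), gap_scale = numeric(0),
                      fac_scale = numeric(0), true_mu_ms = numeric(0),
                      true_gap_effect_ms = numeric(0),
                      true_facilitation_ms = numeric(0),
                      stringsAsFactors = FALSE)
    out$profile <- list()
    return(out)
  }
  rownames(out) <- NULL
  prof_list <- profiles[out$participant_id]
  out$mu_scale <- vapply(prof_list, `[[`, numeric(1), "mu_scale")
  out$gap_scale <- vapply(prof_list, `[[`, numeric(1), "gap_scale")
  out$fac_scale <- vapply(prof_list, `[[`, numeric(1), "fac_scale")
  out$true_mu_ms <- mapply(function(p, a) profile_mu(p, a), prof_list, out$age_months)
  out$true_gap_effect_ms <- mapply(function(p, a) profile_gap_effect(p, a),
                                   prof_list, out$age_months)
  out$true_facilitation_ms <- mapply(function(p, a) profile_facilitation(p, a),
                                     prof_list, out$age_months)
  out$profile <- unname(prof_list)
  out
}
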
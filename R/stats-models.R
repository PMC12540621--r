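#' Random-intercept model of a measure against age
#'
#' Fits `value ~ age_months` with a participant-level random intercept,
#' using all measurements (participants with longitudinal data contribute
#' one summary per wave). Inference on the age slope is Wald-based
#' (`z = b / SE`, normal reference), appropriate at cohort sample sizes.
#' When no participant has repeated measurements the random intercept is
#' unidentified and the fit degrades to ordinary least squares with a
#' warning; singular mixed fits are flagged, not hidden.
#'
#' @param data Data.frame with `participant_id`, `age_months`, and the
#'   outcome column.
#' @param value_col Name of the outcome column (default `"value"`).
#' @return A list of class `mixed_model_fit`: `b`, `se`, `z`, `ci_low`,
#'   `ci_high`, `p`, `random_intercept_variance`, `singular`, `method`
#'   (`"lmm"` or `"ols"`), `n_obs`, `n_participants`.
#' @export
fit_random_intercept_model <- function(data, value_col = "value") {
  stopifnot(all(c("participant_id", "age_months", value_col) %in% names(data)))
  ok <- stats::complete.cases(data$age_months, data[[value_col]])
  d <- data.frame(participant_id = data$participant_id[ok],
                  age_months = data$age_months[ok],
                  value = data[[value_col]][ok])
  if (length(unique(d$participant_id)) < 2L) {
    stop("fit_random_intercept_model: need at least 2 participants")
  }
  if (stats::var(d$value) == 0) {
    warning("constant outcome; slope is 0 by construction")
    return(structure(list(b = 0, se = NA_real_, z = NA_real_,
                          ci_low = 0, ci_high = 0, p = NA_real_,
                          random_intercept_variance = 0, singular = TRUE,
                          method = "degenerate", n_obs = nrow(d),
                          n_participants = length(unique(d$participant_id))),
                     class = "mixed_model_fit"))
  }
  repeated <- any(duplicated(d$participant_id))
  if (repeated) {
    fit <- lme4::lmer(value ~ age_months + (1 | participant_id), data = d,
                      REML = TRUE)
    singular <- lme4::isSingular(fit)
    if (singular) warning("random-intercept fit is singular")
    co <- summary(fit)$coefficients
    b <- co["age_months", "Estimate"]
    se <- co["age_months", "Std. Error"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    ri_var <- vc$vcov[vc$grp == "participant_id"][1]
    method <- "lmm"
  } else {
    warning("no repeated measurements; degrading to ordinary least squares")
    fit <- stats::lm(value ~ age_months, data = d)
    co <- summary(fit)$coefficients
    b <- co["age_months", "Estimate"]
    se <- co["age_months", "Std. Error"]
    ri_var <- NA_real_
    singular <- FALSE
    method <- "ols"
  }
  z <- b / se
  structure(list(b = b, se = se, z = z,
                 ci_low = b - stats::qnorm(0.975) * se,
                 ci_high = b + stats::qnorm(0.975) * se,
                 p = 2 * stats::pnorm(-abs(z)),
                 random_intercept_variance = ri_var,
                 singular = singular, method = method,
                 n_obs = nrow(d),
                 n_participants = length(unique(d$participant_id))),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf(
    "Age slope (%s): b = %.3f ms/month, SE = %.3f, z = %.2f, 95%% CI [%.3f, %.3f], p = %s\n",
    x$method, x$b, x$se, x$z, x$ci_low, x$ci_high,
    format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Holm step-down adjustment
#'
#' Validated front end over the standard step-down Holm procedure: p values
#' sorted ascending are multiplied by `m - i + 1`, monotonicity enforced,
#' capped at 1, and returned in input order.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("holm_adjust: p values must be in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' Paired wave-to-wave comparisons with Holm correction
#'
#' For every pair of waves, compares the measure within participants
#' observed at both (difference taken earlier minus later, so a
#' developmental decline gives positive statistics). The test is a paired
#' t-test, or the Wilcoxon signed-rank test when the paired differences
#' reject a Shapiro-Wilk normality check at `alpha_normality` (rule
#' configurable via `method_rule`). Effect sizes: paired Cohen's d
#' (`mean(diff)/sd(diff)`) for the t-test, matched-pairs rank-biserial
#' correlation for the Wilcoxon. Holm adjustment is applied across the
#' family of contrasts actually tested.
#'
#' @param wide Data.frame or matrix, rows = participants, columns = waves
#'   (in chronological order), values = the measure.
#' @param method_rule `"auto"` (normality check), `"t"`, or `"wilcoxon"`.
#' @param min_pairs Minimum complete pairs per contrast (default 5; smaller
#'   cells are skipped).
#' @param alpha_normality Level of the normality check (default 0.05).
#' @return Data.frame: `contrast`, `test`, `statistic`, `p_raw`, `p_holm`,
#'   `effect_size`, `n_pairs`.
#' @export
paired_condition_comparisons <- function(wide, method_rule = c("auto", "t", "wilcoxon"),
                                         min_pairs = 5, alpha_normality = 0.05) {
  method_rule <- match.arg(method_rule)
  wide <- as.data.frame(wide)
  labs <- colnames(wide)
  k <- ncol(wide)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      ok <- stats::complete.cases(wide[[i]], wide[[j]])
      if (sum(ok) < min_pairs) next
      d <- wide[[i]][ok] - wide[[j]][ok]
      n <- length(d)
      if (all(d == 0)) {
        warning(sprintf("all paired differences zero for %s vs %s; degenerate test",
                        labs[i], labs[j]))
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = paste(labs[i], "vs", labs[j]), test = "degenerate",
          statistic = 0, p_raw = 1, effect_size = 0, n_pairs = n,
          stringsAsFactors = FALSE)
        next
      }
      test <- switch(method_rule,
        t = "paired_t", wilcoxon = "wilcoxon",
        auto = {
          dd <- if (n > 5000) sample(d, 5000) else d
          norm_p <- tryCatch(stats::shapiro.test(dd)$p.value,
                             error = function(e) 1)
          if (norm_p < alpha_normality) "wilcoxon" else "paired_t"
        })
      if (test == "paired_t") {
        tt <- stats::t.test(d)
        stat <- unname(tt$statistic)
        p <- tt$p.value
        eff <- mean(d) / stats::sd(d)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE))
        stat <- unname(wt$statistic)   # V: sum of positive ranks
        p <- wt$p.value
        nz <- sum(d != 0)
        eff <- if (nz == 0) 0 else 2 * stat / (nz * (nz + 1) / 2) - 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste(labs[i], "vs", labs[j]), test = test,
        statistic = stat, p_raw = p, effect_size = eff, n_pairs = n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contrast = character(0), test = character(0),
                      statistic = numeric(0), p_raw = numeric(0),
                      p_holm = numeric(0), effect_size = numeric(0),
                      n_pairs = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_raw)
  out[c("contrast", "test", "statistic", "p_raw", "p_holm",
        "effect_size", "n_pairs")]
}

#' Cross-wave Spearman correlation matrix of a measure
#'
#' For each ordered pair of waves, the Spearman correlation of the measure
#' across participants observed at both waves — the stability/predictive
#' structure of the measure over development. Cells with fewer than
#' `min_pairs` overlapping participants are left absent.
#'
#' @param data Data.frame with `participant_id`, `wave_label`, and the
#'   measure column.
#' @param value_col Name of the measure column (default `"gap_effect_ms"`).
#' @param waves Character vector giving wave order; default = order of first
#'   appearance.
#' @param min_pairs Minimum overlap per cell (default 3).
#' @return A list of class `wave_correlation_matrix` with upper-triangular
#'   matrices `r`, `p`, `n` (dimnames = wave labels).
#' @export
cross_wave_correlation_matrix <- function(data, value_col = "gap_effect_ms",
                                          waves = NULL, min_pairs = 3) {
  stopifnot(all(c("participant_id", "wave_label", value_col) %in% names(data)))
  if (is.null(waves)) waves <- unique(data$wave_label)
  k <- length(waves)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(waves, waves))
  per_wave <- lapply(waves, function(w) {
    d <- data[data$wave_label == w & !is.na(data[[value_col]]), ]
    stats::setNames(d[[value_col]], d$participant_id)
  })
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      common <- intersect(names(per_wave[[i]]), names(per_wave[[j]]))
      nmat[i, j] <- length(common)
      if (length(common) < min_pairs) next
      x <- per_wave[[i]][common]
      y <- per_wave[[j]][common]
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = nmat), class = "wave_correlation_matrix")
}

#' @export
print.wave_correlation_matrix <- function(x, ...) {
  cat("Cross-wave Spearman correlations (r):\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Repeated-measures omnibus test across waves
#'
#' Complete-case repeated-measures ANOVA with the within-subject factor
#' wave/age, delegated to the standard multivariate linear model machinery
#' with Huynh-Feldt sphericity correction. Returns the univariate F with
#' HF-corrected degrees of freedom and p, plus partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`). With two waves sphericity is
#' moot (the F equals the squared paired t).
#'
#' @param data Data.frame with `participant_id`, `wave_label`, and the
#'   outcome column; only participants observed at every wave are used.
#' @param value_col Name of the outcome column (default `"value"`).
#' @param waves Character vector giving wave order; default = order of first
#'   appearance.
#' @return A list of class `omnibus_result`: `F`, `df_num`, `df_den`
#'   (HF-corrected), `p`, `eta_sq_partial`, `epsilon_hf`, `n`.
#' @export
run_omnibus <- function(data, value_col = "value", waves = NULL) {
  stopifnot(all(c("participant_id", "wave_label", value_col) %in% names(data)))
  if (is.null(waves)) waves <- unique(data$wave_label)
  k <- length(waves)
  if (k < 2L) stop("run_omnibus: need at least 2 waves")
  wide <- stats::reshape(
    data.frame(participant_id = data$participant_id,
               wave_label = factor(data$wave_label, levels = waves),
               value = data[[value_col]]),
    idvar = "participant_id", timevar = "wave_label", direction = "wide")
  wide <- wide[stats::complete.cases(wide), ]
  n <- nrow(wide)
  if (n < 3L) stop("run_omnibus: fewer than 3 complete-case participants")
  y <- as.matrix(wide[, paste0("value.", waves)])
  mlm <- stats::lm(y ~ 1)
  idata <- data.frame(wave = factor(waves, levels = waves))
  av <- car::Anova(mlm, idata = idata, idesign = ~wave, type = "III")
  s <- suppressWarnings(summary(av, multivariate = FALSE))  # "HF eps > 1 treated as 1"
  ut <- s$univariate.tests
  row <- grep("wave", rownames(ut))[1]
  ss_eff <- ut[row, "Sum Sq"]
  ss_err <- ut[row, "Error SS"]
  f_val <- ut[row, "F value"]
  df1 <- ut[row, "num Df"]
  df2 <- ut[row, "den Df"]
  p_unc <- ut[row, "Pr(>F)"]
  eps <- 1
  p_out <- p_unc
  pa <- s$pval.adjustments
  if (!is.null(pa) && nrow(pa) > 0 && "HF eps" %in% colnames(pa)) {
    prow <- grep("wave", rownames(pa))[1]
    if (!is.na(prow) && is.finite(pa[prow, "HF eps"])) {
      eps <- min(pa[prow, "HF eps"], 1)
      p_out <- pa[prow, "Pr(>F[HF])"]
    }
  }
  structure(list(F = unname(f_val),
                 df_num = unname(df1 * eps),
                 df_den = unname(df2 * eps),
                 p = unname(p_out),
                 eta_sq_partial = unname(ss_eff / (ss_eff + ss_err)),
                 epsilon_hf = unname(eps),
                 n = n),
            class = "omnibus_result")
}

#' @export
print.omnibus_result <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures omnibus: F(%.3f, %.3f) = %.3f, p = %s, partial eta^2 = %.3f (n = %d)\n",
    x$df_num, x$df_den, x$F, format.pval(x$p, digits = 3),
    x$eta_sq_partial, x$n))
  invisible(x)
}
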
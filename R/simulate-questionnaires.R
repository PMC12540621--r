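#' Synthetic questionnaire item generator
#'
#' Generates item-level caregiver-questionnaire responses whose latent trait
#' is coupled to each measurement's latent gap effect through a Gaussian
#' copula with correlation `rho`. The gap effects are mapped to normal
#' scores, the latent trait is `rho * z_gap + sqrt(1 - rho^2) * noise`, each
#' item loads on the trait (loading 0.6 by default) and is thresholded to
#' its ordinal scale: Likert items to `{1..7}` with equal-mass categories,
#' 3-point problem items to `{0, 1, 2}` with skewed mass (70/20/10%), as
#' problem-behaviour items are in mostly non-clinical samples.
#'
#' Instruments follow the administration ages of the emulated study: the
#' early-childhood temperament form (ECBQ, 39 Likert items) at 18-35 months,
#' the childhood form (CBQ, 87 Likert items) at 36-95 months, and the
#' problem-behaviour checklist (CBCL, 118 three-point items) from 18 months
#' up. Reverse-coded items are stored reversed (`8 - v`), so scoring with
#' [score_subscale()] recovers the positive trait coupling.
#'
#' @param cohort Data.frame with `participant_id`, `age_months`, and a latent
#'   gap-effect column (`true_gap_effect_ms`, falling back to
#'   `gap_effect_ms`); typically a [build_cohort()] table.
#' @param rho Latent trait-to-gap-effect correlation, in `[-1, 1]`.
#' @param seed Optional integer seed.
#' @param loading Item loading on the latent trait, in `(0, 1)`.
#' @param definitions Subscale definitions used only to mark reverse-coded
#'   items; defaults to [default_subscale_definitions()].
#' @return Long data.frame: `participant_id`, `wave_label` (if present in
#'   `cohort`), `age_months`, `instrument`, `item_id`, `response`. The
#'   attribute `"latent"` carries the hidden ground truth (`trait_z`,
#'   `z_gap`) for generator-validation tests.
#' @export
simulate_questionnaires <- function(cohort, rho, seed = NULL, loading = 0.6,
                                    definitions = default_subscale_definitions()) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || abs(rho) > 1) {
    stop("simulate_questionnaires: rho must be a number in [-1, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  gap_col <- if ("true_gap_effect_ms" %in% names(cohort)) "true_gap_effect_ms"
    else if ("gap_effect_ms" %in% names(cohort)) "gap_effect_ms"
    else stop("simulate_questionnaires: cohort needs a gap-effect column")
  n <- nrow(cohort)
  if (n == 0L) {
    out <- data.frame(participant_id = character(0), age_months = numeric(0),
                      instrument = character(0), item_id = character(0),
                      response = integer(0), stringsAsFactors = FALSE)
    attr(out, "latent") <- data.frame(trait_z = numeric(0), z_gap = numeric(0))
    return(out)
  }
  z_gap <- stats::qnorm((rank(cohort[[gap_col]], ties.method = "average") - 0.5) / n)
  trait_z <- rho * z_gap + sqrt(1 - rho^2) * stats::rnorm(n)

  reverse_ids <- unique(unlist(lapply(definitions, `[[`, "reverse_coded_ids")))
  likert_cuts <- stats::qnorm(seq_len(6) / 7)
  cbcl_cuts <- stats::qnorm(c(0.7, 0.9))

  gen_items <- function(rows, instrument, n_items, prefix, scale) {
    if (length(rows) == 0L) return(NULL)
    m <- length(rows)
    lat <- loading * rep(trait_z[rows], times = n_items) +
      sqrt(1 - loading^2) * stats::rnorm(m * n_items)
    item_id <- rep(sprintf("%s_%03d", prefix, seq_len(n_items)), each = m)
    if (scale == "likert_1_7") {
      resp <- findInterval(lat, likert_cuts) + 1L
      rev <- item_id %in% reverse_ids
      resp[rev] <- 8L - resp[rev]
    } else {
      resp <- findInterval(lat, cbcl_cuts)
    }
    df <- data.frame(participant_id = rep(cohort$participant_id[rows], times = n_items),
                     age_months = rep(cohort$age_months[rows], times = n_items),
                     instrument = instrument, item_id = item_id,
                     response = as.integer(resp), stringsAsFactors = FALSE)
    if ("wave_label" %in% names(cohort)) {
      df$wave_label <- rep(cohort$wave_label[rows], times = n_items)
    }
    df
  }

  age <- cohort$age_months
  parts <- list(
    gen_items(which(age >= 18 & age < 36), "ECBQ", 39L, "ecbq", "likert_1_7"),
    gen_items(which(age >= 36 & age < 96), "CBQ", 87L, "cbq", "likert_1_7"),
    gen_items(which(age >= 18), "CBCL", 118L, "cbcl", "three_point_0_2")
  )
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(participant_id = character(0), age_months = numeric(0),
                      instrument = character(0), item_id = character(0),
                      response = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "latent") <- data.frame(participant_id = cohort$participant_id,
                                    age_months = cohort$age_months,
                                    trait_z = trait_z, z_gap = z_gap,
                                    stringsAsFactors = FALSE)
  out
}
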
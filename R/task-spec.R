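#' Gap-Overlap task specification
#'
#' Bundles the timing and geometry parameters of a Gap-Overlap session:
#' sampling rate of the eye tracker, screen extent in visual degrees, the gap
#' lead (how long before peripheral onset the central stimulus disappears in
#' the gap condition), the variable interstimulus interval between fixation
#' confirmation and peripheral onset, the peripheral eccentricity, the
#' response timeout, and the block structure (4 blocks of 12 trials by
#' default, with one optional extra block when too few trials pass the online
#' validity check).
#'
#' @param sampling_rate_hz Eye-tracker sampling rate in Hz (300 or 600 are
#'   typical; any positive value is accepted).
#' @param screen_width_deg,screen_height_deg Screen extent in visual degrees.
#' @param gap_lead_ms Central-stimulus offset lead before peripheral onset in
#'   the gap condition, milliseconds.
#' @param isi_range_ms Length-2 numeric, closed interval (ms) from which the
#'   interstimulus interval between fixation confirmation and peripheral
#'   onset is drawn uniformly.
#' @param peripheral_eccentricity_deg Horizontal eccentricity of the
#'   peripheral stimulus, degrees from screen center.
#' @param peripheral_timeout_ms Response window after peripheral onset, ms.
#' @param trials_per_block,n_blocks Block structure of a standard session.
#' @param extra_block_size Number of trials in the optional extra block.
#' @param min_valid_online Per-condition count of online-valid trials below
#'   which the extra block is triggered.
#' @param fixation_confirm_ms Time from trial start at which central fixation
#'   is taken as confirmed (the ISI clock starts here), ms.
#'
#' @return An object of class `task_spec` (a validated list).
#' @export
#' @examples
#' task <- task_spec()
#' task$gap_lead_ms
task_spec <- function(sampling_rate_hz = 300,
                      screen_width_deg = 51,
                      screen_height_deg = 29,
                      gap_lead_ms = 200,
                      isi_range_ms = c(600, 700),
                      peripheral_eccentricity_deg = 20.8,
                      peripheral_timeout_ms = 2000,
                      trials_per_block = 12,
                      n_blocks = 4,
                      extra_block_size = 12,
                      min_valid_online = 12,
                      fixation_confirm_ms = 400) {
  spec <- list(
    sampling_rate_hz = sampling_rate_hz,
    screen_width_deg = screen_width_deg,
    screen_height_deg = screen_height_deg,
    gap_lead_ms = gap_lead_ms,
    isi_range_ms = as.numeric(isi_range_ms),
    peripheral_eccentricity_deg = peripheral_eccentricity_deg,
    peripheral_timeout_ms = peripheral_timeout_ms,
    trials_per_block = as.integer(trials_per_block),
    n_blocks = as.integer(n_blocks),
    extra_block_size = as.integer(extra_block_size),
    min_valid_online = as.integer(min_valid_online),
    fixation_confirm_ms = fixation_confirm_ms
  )
  class(spec) <- "task_spec"
  validate_task_spec(spec)
}

validate_task_spec <- function(spec) {
  stopifnot(inherits(spec, "task_spec"))
  dur <- c(spec$sampling_rate_hz, spec$screen_width_deg, spec$screen_height_deg,
           spec$gap_lead_ms, spec$peripheral_timeout_ms, spec$fixation_confirm_ms)
  if (any(!is.finite(dur)) || any(dur <= 0)) {
    stop("task_spec: all durations and dimensions must be positive and finite")
  }
  if (length(spec$isi_range_ms) != 2L || spec$isi_range_ms[1] > spec$isi_range_ms[2] ||
      any(spec$isi_range_ms <= 0)) {
    stop("task_spec: isi_range_ms must be a positive interval [lo, hi] with lo <= hi")
  }
  if (spec$trials_per_block < 1L || spec$n_blocks < 1L) {
    stop("task_spec: trials_per_block and n_blocks must be >= 1")
  }
  if ((spec$trials_per_block * spec$n_blocks) %% 3L != 0L) {
    stop("task_spec: trials_per_block * n_blocks must be divisible by 3 (balanced conditions)")
  }
  spec
}

#' @export
print.task_spec <- function(x, ...) {
  cat("Gap-Overlap task specification\n")
  cat(sprintf("  sampling rate: %g Hz; screen: %g x %g deg\n",
              x$sampling_rate_hz, x$screen_width_deg, x$screen_height_deg))
  cat(sprintf("  gap lead: %g ms; ISI: [%g, %g] ms; eccentricity: %g deg\n",
              x$gap_lead_ms, x$isi_range_ms[1], x$isi_range_ms[2],
              x$peripheral_eccentricity_deg))
  cat(sprintf("  %d blocks x %d trials (+%d extra when < %d valid/condition); timeout %g ms\n",
              x$n_blocks, x$trials_per_block, x$extra_block_size,
              x$min_valid_online, x$peripheral_timeout_ms))
  invisible(x)
}

#' Visual angle subtended by a stimulus
#'
#' Converts a physical stimulus size and viewing distance to visual degrees.
#' With `small_angle = TRUE` (the convention for screen-based saccade tasks)
#' the angle is `size / distance` radians; otherwise the exact
#' `2 * atan(size / (2 * distance))` is used.
#'
#' @param size_cm Stimulus extent in cm.
#' @param distance_cm Viewing distance in cm.
#' @param small_angle Use the small-angle approximation (default `TRUE`).
#' @return Visual angle in degrees.
#' @export
#' @examples
#' visual_angle_deg(3, 62) # a 3 cm stimulus at 62 cm: about 2.8 degrees
visual_angle_deg <- function(size_cm, distance_cm, small_angle = TRUE) {
  stopifnot(is.numeric(size_cm), is.numeric(distance_cm), all(distance_cm > 0))
  if (small_angle) {
    (size_cm / distance_cm) * 180 / pi
  } else {
    2 * atan(size_cm / (2 * distance_cm)) * 180 / pi
  }
}
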
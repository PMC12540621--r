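#' Generate the trial schedule for one Gap-Overlap session
#'
#' A standard session has `n_blocks * trials_per_block` trials split equally
#' over the three conditions (gap, overlap, baseline) with left/right
#' peripheral onsets counterbalanced within condition; trial order is
#' randomised within block. When `force_extra_block` is set — emulating a
#' session whose conservative online validity check counted fewer than
#' `min_valid_online` good trials in some condition — one extra block of
#' `extra_block_size` trials is appended.
#'
#' Per-trial timing: the central stimulus appears at 0 ms; central fixation
#' is taken as confirmed at `fixation_confirm_ms`; the interstimulus interval
#' to peripheral onset is drawn uniformly from `isi_range_ms`. In the gap
#' condition the central stimulus goes off `gap_lead_ms` before peripheral
#' onset, in baseline exactly at peripheral onset, and in overlap it stays on
#' through the whole response window.
#'
#' @param task A [task_spec()].
#' @param force_extra_block Append the extra block (default `FALSE`).
#' @param seed Optional integer seed.
#' @return A data.frame of class `trial_schedule` with columns `trial_id`,
#'   `block_index`, `condition`, `side`, `center_onset_ms`,
#'   `center_offset_ms`, `peripheral_onset_ms`.
#' @export
#' @examples
#' sched <- schedule_session(task_spec(), seed = 1)
#' table(sched$condition, sched$side)
schedule_session <- function(task = task_spec(), force_extra_block = FALSE,
                             seed = NULL) {
  validate_task_spec(task)
  if (!is.null(seed)) set.seed(seed)
  conditions <- c("gap", "overlap", "baseline")

  block_trials <- function(block_size) {
    if (block_size %% 3L != 0L) {
      stop("schedule_session: block size must be divisible by 3")
    }
    per_cond <- block_size %/% 3L
    cond <- rep(conditions, each = per_cond)
    # counterbalance sides within condition; odd per-cond counts alternate
    side <- unlist(lapply(seq_along(conditions), function(i) {
      s <- rep(c("left", "right"), length.out = per_cond)
      sample(s)
    }), use.names = FALSE)
    ord <- sample.int(block_size)
    data.frame(condition = cond[ord], side = side[ord], stringsAsFactors = FALSE)
  }

  n_std <- task$n_blocks
  blocks <- lapply(seq_len(n_std), function(b) {
    cbind(block_index = b, block_trials(task$trials_per_block))
  })
  if (isTRUE(force_extra_block)) {
    blocks <- c(blocks, list(cbind(block_index = n_std + 1L,
                                   block_trials(task$extra_block_size))))
  }
  sched <- do.call(rbind, blocks)
  n <- nrow(sched)
  isi <- stats::runif(n, task$isi_range_ms[1], task$isi_range_ms[2])
  peripheral_onset <- task$fixation_confirm_ms + isi
  center_offset <- ifelse(
    sched$condition == "gap", peripheral_onset - task$gap_lead_ms,
    ifelse(sched$condition == "baseline", peripheral_onset,
           peripheral_onset + task$peripheral_timeout_ms))
  out <- data.frame(
    trial_id = sprintf("T%03d", seq_len(n)),
    block_index = sched$block_index,
    condition = sched$condition,
    side = sched$side,
    center_onset_ms = 0,
    center_offset_ms = center_offset,
    peripheral_onset_ms = peripheral_onset,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trial_schedule", "data.frame")
  out
}
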
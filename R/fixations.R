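#' Parameters of the dispersion-based fixation classifier
#'
#' Defaults: dispersion threshold 1.5 degrees (sum of x and y ranges), minimum
#' duration 60 ms, and merging of adjacent fixations separated by less than
#' 75 ms and less than 1 degree.
#'
#' @param dispersion_deg Maximum `(max x - min x) + (max y - min y)` within a
#'   fixation, degrees.
#' @param min_duration_ms Minimum fixation duration, ms.
#' @param merge_gap_ms,merge_distance_deg Adjacent fixations closer than both
#'   limits are merged.
#' @return A list of class `fixation_params`.
#' @export
fixation_params <- function(dispersion_deg = 1.5, min_duration_ms = 60,
                            merge_gap_ms = 75, merge_distance_deg = 1.0) {
  stopifnot(dispersion_deg > 0, min_duration_ms > 0,
            merge_gap_ms >= 0, merge_distance_deg >= 0)
  structure(list(dispersion_deg = dispersion_deg,
                 min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms,
                 merge_distance_deg = merge_distance_deg),
            class = "fixation_params")
}

# binocular average of the valid eyes, NA when neither eye is valid
binocular_average <- function(gaze) {
  lx <- ifelse(gaze$l_valid, gaze$lx_deg, NA_real_)
  ly <- ifelse(gaze$l_valid, gaze$ly_deg, NA_real_)
  rx <- ifelse(gaze$r_valid, gaze$rx_deg, NA_real_)
  ry <- ifelse(gaze$r_valid, gaze$ry_deg, NA_real_)
  x <- rowMeans(cbind(lx, rx), na.rm = TRUE)
  y <- rowMeans(cbind(ly, ry), na.rm = TRUE)
  x[is.nan(x)] <- NA_real_
  y[is.nan(y)] <- NA_real_
  data.frame(t_ms = gaze$t_ms, x = x, y = y)
}

#' Dispersion-based fixation classification (I-DT)
#'
#' Classifies fixations on the binocular-averaged gaze signal (per-sample
#' average of whichever eyes are valid). A maximal run of samples is a
#' fixation when its dispersion — the x range plus the y range — stays at or
#' below the threshold and it spans at least the minimum duration. Windows
#' are grown greedily: a candidate window of minimum duration that exceeds
#' the threshold slides forward one sample; an admissible window is extended
#' until the next sample would break the threshold. Adjacent fixations
#' separated by less than the merge gap and merge distance are merged
#' (centroids combined weighted by sample count). Invalid samples are skipped;
#' an empty or all-invalid recording yields zero fixations.
#'
#' @param gaze A gaze data.frame (`t_ms`, `lx_deg`, `ly_deg`, `rx_deg`,
#'   `ry_deg`, `l_valid`, `r_valid`), as from [simulate_trial_gaze()].
#' @param params A [fixation_params()].
#' @return Data.frame with one row per fixation: `start_ms`, `end_ms`,
#'   `centroid_x_deg`, `centroid_y_deg`, `n_samples`, in time order and
#'   non-overlapping.
#' @export
classify_fixations <- function(gaze, params = fixation_params()) {
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      centroid_x_deg = numeric(0), centroid_y_deg = numeric(0),
                      n_samples = integer(0))
  if (is.null(gaze) || nrow(gaze) == 0L) return(empty)
  avg <- binocular_average(gaze)
  ok <- !is.na(avg$x) & !is.na(avg$y)
  t <- avg$t_ms[ok]; x <- avg$x[ok]; y <- avg$y[ok]
  n <- length(t)
  if (n < 2L) return(empty)

  thr <- params$dispersion_deg
  min_dur <- params$min_duration_ms
  core <- list()   # (start index, end index) of admissible windows
  i <- 1L
  while (i < n) {
    # smallest window from i spanning the minimum duration
    j0 <- i
    while (j0 <= n && t[j0] - t[i] < min_dur) j0 <- j0 + 1L
    if (j0 > n) break
    disp <- (cummax(x[i:n]) - cummin(x[i:n])) + (cummax(y[i:n]) - cummin(y[i:n]))
    if (disp[j0 - i + 1L] > thr) {
      i <- i + 1L
      next
    }
    over <- which(disp > thr)
    jend <- if (length(over) == 0L) n else i + over[1L] - 2L
    core[[length(core) + 1L]] <- c(i, jend)
    i <- jend + 1L
  }
  if (length(core) == 0L) return(empty)

  # boundary refinement: the greedy pass ends a window wherever cumulative
  # dispersion happens to cross the threshold, leaving sub-minimum-duration
  # fragments (e.g. the last few samples before a saccade) unclassified and
  # biasing fixation ends early. Re-attach adjacent samples that stay within
  # the dispersion threshold of the window centroid, without crossing the
  # neighbouring fixation.
  k <- length(core)
  fix <- vector("list", k)
  for (f in seq_len(k)) {
    i0 <- core[[f]][1]; j0 <- core[[f]][2]
    cx <- mean(x[i0:j0]); cy <- mean(y[i0:j0])
    lo_lim <- if (f > 1L) core[[f - 1L]][2] + 1L else 1L
    hi_lim <- if (f < k) core[[f + 1L]][1] - 1L else n
    while (j0 < hi_lim &&
           sqrt((x[j0 + 1L] - cx)^2 + (y[j0 + 1L] - cy)^2) <= thr) {
      j0 <- j0 + 1L
    }
    while (i0 > lo_lim &&
           sqrt((x[i0 - 1L] - cx)^2 + (y[i0 - 1L] - cy)^2) <= thr) {
      i0 <- i0 - 1L
    }
    idx <- i0:j0
    fix[[f]] <- c(t[i0], t[j0], mean(x[idx]), mean(y[idx]), length(idx))
  }
  m <- do.call(rbind, fix)
  out <- data.frame(start_ms = m[, 1], end_ms = m[, 2],
                    centroid_x_deg = m[, 3], centroid_y_deg = m[, 4],
                    n_samples = as.integer(m[, 5]))
  merge_fixations(out, params)
}

merge_fixations <- function(fx, params) {
  if (nrow(fx) < 2L) return(fx)
  out <- fx[1, ]
  for (k in 2:nrow(fx)) {
    last <- nrow(out)
    gap <- fx$start_ms[k] - out$end_ms[last]
    dist <- sqrt((fx$centroid_x_deg[k] - out$centroid_x_deg[last])^2 +
                 (fx$centroid_y_deg[k] - out$centroid_y_deg[last])^2)
    if (gap < params$merge_gap_ms && dist < params$merge_distance_deg) {
      ntot <- out$n_samples[last] + fx$n_samples[k]
      out$centroid_x_deg[last] <-
        (out$centroid_x_deg[last] * out$n_samples[last] +
         fx$centroid_x_deg[k] * fx$n_samples[k]) / ntot
      out$centroid_y_deg[last] <-
        (out$centroid_y_deg[last] * out$n_samples[last] +
         fx$centroid_y_deg[k] * fx$n_samples[k]) / ntot
      out$end_ms[last] <- fx$end_ms[k]
      out$n_samples[last] <- ntot
    } else {
      out <- rbind(out, fx[k, ])
    }
  }
  rownames(out) <- NULL
  out
}
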
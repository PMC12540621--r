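#' RMS sample-to-sample precision of a gaze recording
#'
#' Precision is computed per eye as the median, across a 0.1 s moving window
#' stepped one sample at a time, of the root-mean-square of sample-to-sample
#' deviations: within each window the horizontal and vertical RMS deviations
#' over consecutive valid sample pairs are combined by Pythagoras
#' (`sqrt(rms_x^2 + rms_y^2)`; with equal pair counts this equals the RMS of
#' the Euclidean step lengths). The trial value is the mean of the two eyes'
#' medians, or the single available eye's median when the other eye has no
#' usable window; `NA` when neither eye does.
#'
#' @param gaze A gaze data.frame (`t_ms`, per-eye positions and validity).
#' @param window_ms Moving-window length, ms (default 100).
#' @return RMS-S2S precision in degrees, or `NA_real_`.
#' @export
compute_precision <- function(gaze, window_ms = 100) {
  if (is.null(gaze) || nrow(gaze) < 2L) return(NA_real_)
  dt <- stats::median(diff(gaze$t_ms))
  w <- max(2L, as.integer(round(window_ms / dt)))
  eye <- function(x, y, valid) {
    n <- length(x)
    if (n < 2L) return(NA_real_)
    dx <- diff(x); dy <- diff(y)
    pair_ok <- valid[-n] & valid[-1] & !is.na(dx) & !is.na(dy)
    s <- ifelse(pair_ok, dx^2 + dy^2, 0)
    cnt <- as.numeric(pair_ok)
    if (n <= w) {
      tot <- sum(cnt)
      if (tot == 0) return(NA_real_)
      return(sqrt(sum(s) / tot))
    }
    cs <- cumsum(s); cc <- cumsum(cnt)
    npairs <- w - 1L
    starts <- seq_len(n - w + 1L)          # window k covers diffs k .. k+w-2
    hi <- starts + npairs - 1L
    sums <- cs[hi] - c(0, cs)[starts]
    cnts <- cc[hi] - c(0, cc)[starts]
    usable <- cnts > 0
    if (!any(usable)) return(NA_real_)
    stats::median(sqrt(sums[usable] / cnts[usable]))
  }
  left <- eye(gaze$lx_deg, gaze$ly_deg, gaze$l_valid)
  right <- eye(gaze$rx_deg, gaze$ry_deg, gaze$r_valid)
  vals <- c(left, right)
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Proportion of data loss in a gaze recording
#'
#' Per eye, the fraction of samples flagged invalid; the trial value is the
#' mean over the two eyes.
#'
#' @param gaze A gaze data.frame with `l_valid`, `r_valid`.
#' @return Proportion in `[0, 1]`.
#' @export
compute_data_loss <- function(gaze) {
  if (is.null(gaze) || nrow(gaze) == 0L) {
    stop("compute_data_loss: empty recording")
  }
  mean(c(mean(!gaze$l_valid), mean(!gaze$r_valid)))
}

#' Per-trial quality metrics
#'
#' Convenience wrapper computing both [compute_precision()] and
#' [compute_data_loss()].
#'
#' @param gaze A gaze data.frame.
#' @param window_ms Precision window, ms.
#' @return One-row data.frame: `rms_s2s_deg`, `data_loss_prop`.
#' @export
trial_qc <- function(gaze, window_ms = 100) {
  data.frame(rms_s2s_deg = compute_precision(gaze, window_ms),
             data_loss_prop = compute_data_loss(gaze))
}
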
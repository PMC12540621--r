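#' Write and read gaze-sample streams as tab-separated files
#'
#' One row per sample with columns `trial_id`, `t_ms`, `lx_deg`, `ly_deg`,
#' `rx_deg`, `ry_deg`, `l_valid`, `r_valid`; validity flags are written as
#' 0/1 and invalid positions as `nan`.
#'
#' @param gaze_list Named list of per-trial gaze data.frames (as produced by
#'   [simulate_session_gaze()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_tsv <- function(gaze_list, path) {
  all_rows <- data.table::rbindlist(gaze_list)
  all_rows$l_valid <- as.integer(all_rows$l_valid)
  all_rows$r_valid <- as.integer(all_rows$r_valid)
  data.table::fwrite(all_rows, path, sep = "\t", na = "nan", quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @return `read_gaze_tsv`: a named list of per-trial gaze data.frames.
#' @export
read_gaze_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", na.strings = "nan",
                         data.table = FALSE)
  d$l_valid <- as.logical(d$l_valid)
  d$r_valid <- as.logical(d$r_valid)
  split(d, factor(d$trial_id, levels = unique(d$trial_id)))
}
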
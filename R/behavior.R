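#' Time to peak force after the Go cue
#'
#' Locates the maximum of the squeeze-bulb pressure trace over the samples at
#' or after the Go cue and returns its latency relative to the cue, in ms.
#' Ties are broken toward the earliest sample (first attainment of maximum
#' force). If the maximum falls on the final sample the trial may be
#' truncated; a `truncated` attribute flags this.
#'
#' @param pressure Numeric pressure series (arbitrary units).
#' @param fs_hz Sampling rate in Hz.
#' @param go_onset_ms Go-cue time in ms from the start of the series.
#' @param smooth_ms Optional moving-average window (ms) applied before the
#'   argmax; default 0 (no smoothing).
#' @return Peak time t3 - t1 in ms (numeric scalar), with attribute
#'   `truncated` (logical).
#' @export
compute_peak_time <- function(pressure, fs_hz, go_onset_ms, smooth_ms = 0) {
  stopifnot(is.numeric(pressure), fs_hz > 0, go_onset_ms >= 0)
  go_idx <- floor(go_onset_ms * fs_hz / 1000) + 1L
  if (go_idx > length(pressure))
    stop("pressure trace contains no samples after the Go cue")
  post <- pressure[go_idx:length(pressure)]
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms * fs_hz / 1000))
    post <- stats::filter(post, rep(1 / w, w), sides = 2)
    post[is.na(post)] <- -Inf
    post <- as.numeric(post)
  }
  if (max(post) == min(post))
    stop("degenerate pressure trace: constant after the Go cue")
  pk <- which.max(post)                       # earliest maximum
  out <- (pk - 1L) * 1000 / fs_hz
  attr(out, "truncated") <- (pk == length(post))
  out
}

#' Motor vigor from peak time
#'
#' Motor vigor is the inverse of the time to reach maximum force after the
#' Go cue: `mv = 1 / peak_time_ms`, in 1/ms.
#'
#' @param peak_time_ms Positive peak time in ms.
#' @return Motor vigor in 1/ms.
#' @export
compute_mv <- function(peak_time_ms) {
  if (any(!is.finite(peak_time_ms)) || any(peak_time_ms <= 0))
    stop("peak_time_ms must be positive and finite")
  1 / peak_time_ms
}

#' Append peak time and motor vigor to a trials table
#'
#' Runs [compute_peak_time()] and [compute_mv()] on each trial of a cohort
#' and appends `peak_time_ms` and `mv` columns.
#'
#' @param cohort A `synthetic_cohort` (see [generate_cohort()]) or a list
#'   with `trials` (data frame) and `pressure` (list of numeric traces).
#' @return The trials data frame with `peak_time_ms` and `mv` columns.
#' @export
add_mv <- function(cohort) {
  tr <- cohort$trials
  pk <- vapply(seq_len(nrow(tr)), function(i) {
    as.numeric(compute_peak_time(cohort$pressure[[i]], tr$fs_hz[i],
                                 tr$go_onset_ms[i]))
  }, numeric(1))
  tr$peak_time_ms <- pk
  tr$mv <- compute_mv(pk)
  tr
}
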
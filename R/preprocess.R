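#' Band-pass filter a recording (zero phase)
#'
#' Filters every channel with a Butterworth band-pass applied forward and
#' backward (double pass), giving zero net phase shift.  The filter is
#' applied to the continuous recording, not per analysis window, so that
#' short-segment transients never sit inside an analysis window; callers
#' should still discard `edge_trim_s` seconds at each end of the record
#' (see [baseline_corrected_rms()]).
#'
#' @param rec An [emg_recording()].
#' @param low_hz,high_hz Band edges in Hz (defaults 20 and 400, the
#'   standard surface-EMG analysis band).
#' @param order Butterworth prototype order (default 2).
#' @return A filtered `emg_recording` of the same shape, with the filter
#'   settings recorded in `meta$filter`.
#' @export
emg_bandpass <- function(rec, low_hz = 20, high_hz = 400, order = 2) {
  stopifnot(inherits(rec, "emg_recording"))
  if (high_hz >= rec$fs / 2) {
    stop("`high_hz` must be below Nyquist (fs/2)", call. = FALSE)
  }
  coef <- butter_bandpass(low_hz, high_hz, rec$fs, order)
  out <- rec$signal
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- filtfilt_signal(coef, rec$signal[ch, ])
  }
  rec$signal <- out
  rec$meta$filter <- list(low_hz = low_hz, high_hz = high_hz, order = order,
                          double_pass = TRUE)
  rec
}

#' Root mean square of a signal window
#'
#' @param signal_window Non-empty numeric vector.
#' @return `sqrt(mean(signal_window^2))`.
#' @export
channel_rms <- function(signal_window) {
  if (length(signal_window) == 0 || !is.numeric(signal_window)) {
    stop("signal window must be a non-empty numeric vector", call. = FALSE)
  }
  sqrt(mean(signal_window^2))
}

#' Baseline-corrected per-channel RMS for one trial
#'
#' For each channel, computes RMS over the trial's active window minus RMS
#' over its rest window (the resting-state baseline, capturing background
#' noise and spontaneous activity).  By default, negative differences are
#' floored at zero: negative "activation" is physically meaningless and
#' would corrupt the centroid weights.  Set `floor_at_zero = FALSE` to keep
#' signed values.
#'
#' Both windows are trimmed away from the record edges by `edge_trim_s`
#' seconds to exclude filter edge transients; a window that would overlap
#' the trimmed margin is an error.
#'
#' @param trial A [task_trial()].
#' @param rec A band-pass filtered [emg_recording()].
#' @param floor_at_zero Logical, floor negative differences at 0
#'   (default `TRUE`).
#' @param edge_trim_s Seconds excluded at each end of the record
#'   (default 0.25).
#' @return Numeric vector, one value per channel.
#' @export
baseline_corrected_rms <- function(trial, rec, floor_at_zero = TRUE,
                                   edge_trim_s = 0.25) {
  stopifnot(inherits(trial, "task_trial"), inherits(rec, "emg_recording"))
  n <- ncol(rec$signal)
  margin <- round(edge_trim_s * rec$fs)
  lo <- 1 + margin
  hi <- n - margin
  for (w in list(trial$active_window, trial$rest_window)) {
    if (w[1] < lo || w[2] > hi) {
      stop(sprintf(paste0("trial window [%d, %d] is outside the usable range ",
                          "[%d, %d] (record length %d, edge trim %.3g s)"),
                   w[1], w[2], lo, hi, n, edge_trim_s), call. = FALSE)
    }
  }
  act <- rec$signal[, trial$active_window[1]:trial$active_window[2],
                    drop = FALSE]
  rst <- rec$signal[, trial$rest_window[1]:trial$rest_window[2], drop = FALSE]
  d <- sqrt(rowMeans(act^2)) - sqrt(rowMeans(rst^2))
  if (floor_at_zero) d <- pmax(d, 0)
  d
}

#' Average per-channel RMS vectors across repetitions
#'
#' @param per_rep_rms List of equal-length numeric vectors (one per
#'   repetition).
#' @return Elementwise arithmetic mean.
#' @export
average_repetitions <- function(per_rep_rms) {
  if (!is.list(per_rep_rms) || length(per_rep_rms) < 1) {
    stop("need at least one repetition", call. = FALSE)
  }
  lens <- vapply(per_rep_rms, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("repetition vectors have mismatched lengths", call. = FALSE)
  }
  Reduce(`+`, per_rep_rms) / length(per_rep_rms)
}

#' Mean RMS across all grid channels
#'
#' The scalar effort-level measure: the arithmetic mean of the per-channel
#' (baseline-corrected) RMS values over the whole grid.
#'
#' @param map_values Non-empty numeric vector of per-channel values.
#' @return Scalar mean.
#' @export
mean_grid_rms <- function(map_values) {
  if (length(map_values) == 0) stop("empty channel vector", call. = FALSE)
  mean(map_values)
}

#' Normalize per-condition mean RMS within a subject
#'
#' Divides every condition's mean-RMS value by the subject's four-finger,
#' high-effort value (the reference contraction), which therefore maps
#' to 1.  Input and output are data frames with columns `finger`, `effort`
#' (optionally `constraint` and others, preserved) and `mean_rms`; the
#' output gains a `norm_rms` column.
#'
#' @param tab Data frame with at least `finger`, `effort`, `mean_rms`.
#' @return `tab` with an added `norm_rms` column.
#' @export
normalize_subject_effort <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("finger", "effort", "mean_rms") %in% names(tab)))
  ref <- tab$mean_rms[tab$finger == "four" & tab$effort == "high"]
  if (length(ref) == 0) {
    stop("reference condition (four-finger, high effort) absent", call. = FALSE)
  }
  ref <- mean(ref)
  if (!is.finite(ref) || ref <= 0) {
    stop("reference condition mean RMS must be positive", call. = FALSE)
  }
  tab$norm_rms <- tab$mean_rms / ref
  tab
}

#' Per-condition averaged RMS vector from an annotated recording
#'
#' Convenience wrapper for the standard chain on one recording: for each
#' repetition of the (single) condition annotated in the recording, compute
#' the baseline-corrected per-channel RMS, then average over repetitions.
#'
#' @param rec A band-pass filtered [emg_recording()] whose trials all share
#'   one condition.
#' @inheritParams baseline_corrected_rms
#' @return Numeric per-channel vector (repetition average).
#' @export
condition_rms <- function(rec, floor_at_zero = TRUE, edge_trim_s = 0.25) {
  stopifnot(inherits(rec, "emg_recording"))
  if (length(rec$trials) == 0) stop("recording has no trial annotations",
                                    call. = FALSE)
  per_rep <- lapply(rec$trials, baseline_corrected_rms, rec = rec,
                    floor_at_zero = floor_at_zero, edge_trim_s = edge_trim_s)
  average_repetitions(per_rep)
}
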
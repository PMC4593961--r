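#' Multichannel surface-EMG recording container
#'
#' Wraps a channels-by-samples signal block with its sampling rate and the
#' task-trial annotations needed for window-based analysis.  Channel count
#' must match an electrode grid; channel order is the grid's row-major
#' order.
#'
#' @param signal Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz (2000 for the standard protocol).
#' @param trials List of [task_trial()] annotations (may be empty).
#' @param grid Optional `electrode_grid`; if given, its channel count must
#'   match `nrow(signal)`.
#' @param meta Optional named list of free-form metadata (seed, condition,
#'   provenance); round-tripped by the file I/O.
#' @return Object of class `emg_recording`.
#' @export
emg_recording <- function(signal, fs, trials = list(), grid = NULL,
                          meta = list()) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  }
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "electrode_grid"))
    if (nrow(signal) != n_channels(grid)) {
      stop(sprintf("signal has %d channels but grid has %d",
                   nrow(signal), n_channels(grid)), call. = FALSE)
    }
  }
  for (tr in trials) stopifnot(inherits(tr, "task_trial"))
  structure(
    list(signal = signal, fs = fs, trials = trials, grid = grid, meta = meta),
    class = "emg_recording"
  )
}

#' Task-trial annotation
#'
#' One repetition of the finger-extension protocol: a steady 5-s active
#' window preceded by a rest segment from which the 2-s baseline window is
#' taken.  Windows are `[start, end]` sample indices (1-based, inclusive)
#' and must be disjoint.
#'
#' @param finger One of `"index"`, `"middle"`, `"ring"`, `"little"`,
#'   `"four"`.
#' @param effort `"high"` or `"low"`.
#' @param constraint `"dynamic"` or `"static"`.
#' @param active_window Length-2 integer, active-window sample bounds.
#' @param rest_window Length-2 integer, rest (baseline) window bounds.
#' @param repetition Repetition number (1--3 in the standard protocol).
#' @return Object of class `task_trial`.
#' @export
task_trial <- function(finger, effort, constraint, active_window, rest_window,
                       repetition = 1L) {
  finger <- match.arg(finger, c("index", "middle", "ring", "little", "four"))
  effort <- match.arg(effort, c("high", "low"))
  constraint <- match.arg(constraint, c("dynamic", "static"))
  aw <- as.integer(active_window); rw <- as.integer(rest_window)
  if (length(aw) != 2L || length(rw) != 2L || aw[1] > aw[2] || rw[1] > rw[2]) {
    stop("windows must be increasing [start, end] sample pairs", call. = FALSE)
  }
  if (max(rw[1], aw[1]) <= min(rw[2], aw[2])) {
    stop("active and rest windows must be disjoint", call. = FALSE)
  }
  structure(
    list(finger = finger, effort = effort, constraint = constraint,
         active_window = aw, rest_window = rw,
         repetition = as.integer(repetition)),
    class = "task_trial"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz, %d trial(s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, length(x$trials)))
  invisible(x)
}

trials_to_df <- function(trials) {
  if (length(trials) == 0) {
    return(data.frame(finger = character(), effort = character(),
                      constraint = character(), repetition = integer(),
                      active_start = integer(), active_end = integer(),
                      rest_start = integer(), rest_end = integer()))
  }
  do.call(rbind, lapply(trials, function(tr) {
    data.frame(finger = tr$finger, effort = tr$effort,
               constraint = tr$constraint, repetition = tr$repetition,
               active_start = tr$active_window[1],
               active_end = tr$active_window[2],
               rest_start = tr$rest_window[1], rest_end = tr$rest_window[2],
               stringsAsFactors = FALSE)
  }))
}

df_to_trials <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    task_trial(df$finger[i], df$effort[i], df$constraint[i],
               c(df$active_start[i], df$active_end[i]),
               c(df$rest_start[i], df$rest_end[i]),
               repetition = df$repetition[i])
  })
}

#' Write / read a recording as delimited text plus a metadata sidecar
#'
#' The signal is written as a tab-separated numeric matrix, one column per
#' channel, header row naming channels `R<row>C<col>` (or `CH<k>` when no
#' grid is attached).  A JSON sidecar (`<path>.meta.json`) stores the
#' sampling rate, the grid definition, the trial annotation table (window
#' bounds in samples) and any free-form metadata; the sidecar round-trips
#' bit-exactly, the signal to text formatting precision.
#'
#' @param rec An `emg_recording`.
#' @param path Path of the signal matrix file; the sidecar path is derived
#'   from it.
#' @return `write_recording` invisibly returns `path`; `read_recording`
#'   returns an `emg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  nm <- if (!is.null(rec$grid)) rec$grid$channels$name
        else sprintf("CH%d", seq_len(nrow(rec$signal)))
  m <- t(rec$signal)
  colnames(m) <- nm
  data.table::fwrite(data.table::as.data.table(m), path, sep = "\t")
  side <- list(
    fs = rec$fs,
    n_channels = nrow(rec$signal),
    n_samples = ncol(rec$signal),
    grid = if (!is.null(rec$grid)) list(
      n_rows = rec$grid$n_rows, n_cols = rec$grid$n_cols,
      col_span_percent = rec$grid$col_span_percent),
    trials = trials_to_df(rec$trials),
    meta = rec$meta
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- as.matrix(data.table::fread(path, sep = "\t"))
  grid <- NULL
  if (!is.null(side$grid)) {
    grid <- build_grid(side$grid$n_rows, side$grid$n_cols,
                       unlist(side$grid$col_span_percent))
  }
  trials <- if (is.data.frame(side$trials) && nrow(side$trials) > 0) {
    df_to_trials(side$trials)
  } else list()
  meta <- side$meta
  if (is.null(meta)) meta <- list()
  emg_recording(t(m), fs = as.numeric(side$fs), trials = trials,
                grid = grid, meta = meta)
}
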
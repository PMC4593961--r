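#' Forearm geometry descriptor
#'
#' Records the physical dimensions of the forearm segment covered by an
#' electrode grid: the proximal--distal span between bony landmarks
#' (olecranon process to ulnar styloid) and the circumference at each
#' electrode row.  All downstream analysis is performed in *relative*
#' coordinates (% length, % circumference); the geometry is metadata that
#' lets maps from different forearms be compared on a common frame.
#'
#' @param length_mm Positive scalar, landmark-to-landmark forearm length in mm.
#' @param circumference_mm_by_row Numeric vector of positive per-row
#'   circumferences in mm (proximal row first). Typically non-increasing
#'   proximal to distal, but this is not enforced.
#' @return An object of class `forearm_geometry`.
#' @examples
#' forearm_geometry(260, seq(270, 180, length.out = 7))
#' @export
forearm_geometry <- function(length_mm, circumference_mm_by_row) {
  if (!is.numeric(length_mm) || length(length_mm) != 1L || !is.finite(length_mm) ||
      length_mm <= 0) {
    stop("`length_mm` must be a single positive number", call. = FALSE)
  }
  circ <- as.numeric(circumference_mm_by_row)
  if (length(circ) < 1L || any(!is.finite(circ)) || any(circ <= 0)) {
    stop("`circumference_mm_by_row` must be positive and finite", call. = FALSE)
  }
  structure(
    list(length_mm = as.numeric(length_mm), circumference_mm_by_row = circ),
    class = "forearm_geometry"
  )
}

#' Build an electrode grid in relative forearm coordinates
#'
#' Constructs the layout model of a rows-by-columns surface-electrode grid
#' wrapped around the forearm.  Rows sit at the centers of `n_rows`
#' equal proximal--distal segments, so row `j` (row 1 most proximal, at the
#' olecranon side) has longitudinal coordinate
#' `y_j = 100 * (j - 0.5) / n_rows` percent of forearm length.  Columns are
#' equally spaced in percent of circumference across `col_span_percent`.
#'
#' The circumferential axis is *linear*: 0% is the medial seam of the
#' forearm and coordinates increase over the flexor side, across the
#' extensor side, back to 100% at the seam.  No circular arithmetic is ever
#' applied downstream; the centroid is a plain linear weighted mean on this
#' axis.  When the span covers the full circumference (`c(0, 100)`, the
#' default), the 0% and 100% points coincide physically, so `n_cols`
#' electrodes are placed with wrap-around spacing `span / n_cols` starting
#' at the span's lower edge (no electrode is duplicated at the seam).  For a
#' partial span the columns are spaced end-inclusively,
#' `span / (n_cols - 1)`.
#'
#' Channels are numbered row-major: channel `(row - 1) * n_cols + col`,
#' named `R<row>C<col>`.
#'
#' @param n_rows Number of electrode rows (>= 1).
#' @param n_cols Number of electrodes per row (>= 2).
#' @param col_span_percent Length-2 numeric, circumferential span in percent,
#'   within `[0, 100]`. Default full circumference `c(0, 100)`.
#' @param geometry Optional [forearm_geometry()] to attach as metadata; if
#'   supplied, its circumference vector must have `n_rows` entries.
#' @return An object of class `electrode_grid` with fields `n_rows`,
#'   `n_cols`, `x_percent` (per-column circumference coordinate),
#'   `y_percent` (per-row length coordinate), `channels` (a data.frame with
#'   `channel`, `row`, `col`, `x`, `y`, `name`).
#' @examples
#' g <- build_grid(7, 9)        # the 63-channel full-forearm configuration
#' g$y_percent                  # 7.14, 21.4, ..., 92.9 (% forearm length)
#' channel_coordinates(g, 1)
#' @export
build_grid <- function(n_rows, n_cols, col_span_percent = c(0, 100),
                       geometry = NULL) {
  if (!is.numeric(n_rows) || length(n_rows) != 1L || n_rows < 1 ||
      n_rows != round(n_rows)) {
    stop("`n_rows` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_cols) || length(n_cols) != 1L || n_cols < 2 ||
      n_cols != round(n_cols)) {
    stop("`n_cols` must be an integer >= 2", call. = FALSE)
  }
  span <- as.numeric(col_span_percent)
  if (length(span) != 2L || any(!is.finite(span)) || span[1] >= span[2] ||
      span[1] < 0 || span[2] > 100) {
    stop("`col_span_percent` must be an increasing pair within [0, 100]",
         call. = FALSE)
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  full_wrap <- isTRUE(all.equal(span[2] - span[1], 100))
  if (full_wrap) {
    # 0% and 100% coincide on the circumference: wrap-around spacing
    x <- span[1] + (seq_len(n_cols) - 1) * (span[2] - span[1]) / n_cols
  } else {
    x <- span[1] + (seq_len(n_cols) - 1) * (span[2] - span[1]) / (n_cols - 1)
  }
  y <- 100 * (seq_len(n_rows) - 0.5) / n_rows
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "forearm_geometry"))
    if (length(geometry$circumference_mm_by_row) != n_rows) {
      stop("geometry circumference vector must have one entry per row",
           call. = FALSE)
    }
  }
  row_idx <- rep(seq_len(n_rows), each = n_cols)
  col_idx <- rep(seq_len(n_cols), times = n_rows)
  channels <- data.frame(
    channel = seq_len(n_rows * n_cols),
    row = row_idx,
    col = col_idx,
    x = x[col_idx],
    y = y[row_idx],
    name = sprintf("R%dC%d", row_idx, col_idx),
    stringsAsFactors = FALSE
  )
  structure(
    list(n_rows = n_rows, n_cols = n_cols, col_span_percent = span,
         x_percent = x, y_percent = y, channels = channels,
         geometry = geometry),
    class = "electrode_grid"
  )
}

#' Number of channels of a grid
#' @param grid An [build_grid()] object.
#' @return Integer channel count (`n_rows * n_cols`).
#' @export
n_channels <- function(grid) {
  stopifnot(inherits(grid, "electrode_grid"))
  grid$n_rows * grid$n_cols
}

#' Relative coordinates of one channel
#'
#' Returns the `(x, y)` pair (percent circumference, percent length) used as
#' the weight location of this channel in the map-centroid computation.
#'
#' @param grid An [build_grid()] object.
#' @param channel Channel index in `1:n_channels(grid)` (row-major order).
#' @return Named numeric vector `c(x = , y = )` in percent.
#' @export
channel_coordinates <- function(grid, channel) {
  stopifnot(inherits(grid, "electrode_grid"))
  if (!is.numeric(channel) || length(channel) != 1L ||
      channel != round(channel) || channel < 1 || channel > n_channels(grid)) {
    stop(sprintf("channel must be an integer in 1..%d", n_channels(grid)),
         call. = FALSE)
  }
  ch <- grid$channels[channel, ]
  c(x = ch$x, y = ch$y)
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %d x %d (%d channels)\n",
              x$n_rows, x$n_cols, n_channels(x)))
  cat(sprintf("  rows (y, %% length): %s\n",
              paste(sprintf("%.2f", x$y_percent), collapse = ", ")))
  cat(sprintf("  col span (%% circumference): [%g, %g]\n",
              x$col_span_percent[1], x$col_span_percent[2]))
  invisible(x)
}

#' @export
as.data.frame.electrode_grid <- function(x, ...) x$channels

#' Write / read a grid configuration file
#'
#' Plain-text (JSON) serialization of the grid definition: rows, columns,
#' circumferential span, and optional forearm geometry, plus the full
#' coordinate table for human inspection.  Reading reconstructs the grid
#' from the definition fields (the coordinate table is redundant).
#'
#' @param grid An `electrode_grid`.
#' @param path File path.
#' @return `write_grid_config` invisibly returns `path`; `read_grid_config`
#'   returns an `electrode_grid`.
#' @export
write_grid_config <- function(grid, path) {
  stopifnot(inherits(grid, "electrode_grid"))
  obj <- list(
    n_rows = grid$n_rows,
    n_cols = grid$n_cols,
    col_span_percent = grid$col_span_percent,
    geometry = if (!is.null(grid$geometry)) {
      list(length_mm = grid$geometry$length_mm,
           circumference_mm_by_row = grid$geometry$circumference_mm_by_row)
    },
    coordinate_units = "percent",
    convention = paste("row 1 proximal (olecranon side); y increases distally;",
                       "x linear on [0,100) with seam at medial forearm"),
    channels = grid$channels
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_grid_config
#' @export
read_grid_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- NULL
  if (!is.null(obj$geometry)) {
    geom <- forearm_geometry(obj$geometry$length_mm,
                             obj$geometry$circumference_mm_by_row)
  }
  build_grid(obj$n_rows, obj$n_cols, unlist(obj$col_span_percent),
             geometry = geom)
}
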
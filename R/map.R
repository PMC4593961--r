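#' Arrange a per-channel RMS vector into a grid map
#'
#' @param per_channel_rms Numeric vector, one value per grid channel in the
#'   grid's row-major channel order.
#' @param grid An [build_grid()] object.
#' @param condition Optional condition label attached to the map.
#' @return Object of class `rms_map`: a `n_rows x n_cols` matrix in
#'   `$values` with the grid and label attached.
#' @export
build_map <- function(per_channel_rms, grid, condition = NA_character_) {
  stopifnot(inherits(grid, "electrode_grid"))
  v <- as.numeric(per_channel_rms)
  if (length(v) != n_channels(grid)) {
    stop(sprintf("expected %d channel values, got %d", n_channels(grid),
                 length(v)), call. = FALSE)
  }
  m <- matrix(v, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  rownames(m) <- sprintf("R%d", seq_len(grid$n_rows))
  colnames(m) <- sprintf("C%d", seq_len(grid$n_cols))
  structure(list(values = m, grid = grid, condition = condition,
                 normalized = FALSE),
            class = "rms_map")
}

#' @export
print.rms_map <- function(x, ...) {
  cat(sprintf("<rms_map%s> %d x %d, condition: %s\n",
              if (isTRUE(x$normalized)) " (normalized)" else "",
              nrow(x$values), ncol(x$values),
              if (is.na(x$condition)) "<none>" else x$condition))
  print(round(x$values, 4))
  invisible(x)
}

#' Activation-map centroid (amplitude-weighted barycenter)
#'
#' The centroid of an RMS map is the RMS-weighted mean of the channel
#' coordinates,
#' \deqn{C_x = \frac{\sum_{ij} RMS_{ij} x_i}{\sum_{ij} RMS_{ij}}, \qquad
#'       C_y = \frac{\sum_{ij} RMS_{ij} y_j}{\sum_{ij} RMS_{ij}},}
#' with \eqn{x} in percent forearm circumference and \eqn{y} in percent
#' forearm length.  It locates the center of the active muscle region and
#' is invariant to global rescaling of the map.  The x axis is treated as
#' linear (no circular mean); the standard grid places the seam at the
#' medial forearm, far from the extensor activation.
#'
#' @param map An `rms_map` with at least one strictly positive element.
#' @return Named numeric `c(cx = , cy = )` in percent.
#' @export
map_centroid <- function(map) {
  stopifnot(inherits(map, "rms_map"))
  v <- map$values
  if (any(v < 0)) stop("map has negative values; centroid weights must be
 non-negative", call. = FALSE)
  tot <- sum(v)
  if (tot <= 0) {
    stop("undefined centroid: map has no strictly positive element",
         call. = FALSE)
  }
  xs <- map$grid$x_percent  # per column
  ys <- map$grid$y_percent  # per row
  cx <- sum(v * matrix(xs, nrow(v), ncol(v), byrow = TRUE)) / tot
  cy <- sum(v * matrix(ys, nrow(v), ncol(v))) / tot
  c(cx = cx, cy = cy)
}

#' Normalize a map to unit maximum
#'
#' Divides every element by the map's maximum, so the maximum becomes 1.
#' An all-zero map cannot be normalized; it is returned unchanged with
#' `degenerate = TRUE` and must be excluded from SSD comparisons.
#'
#' @param map A non-negative `rms_map`.
#' @return An `rms_map` with `normalized = TRUE` (and `degenerate` flag).
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "rms_map"))
  if (any(map$values < 0)) stop("map must be non-negative", call. = FALSE)
  mx <- max(map$values)
  if (mx == 0) {
    map$normalized <- TRUE
    map$degenerate <- TRUE
    return(map)
  }
  map$values <- map$values / mx
  map$normalized <- TRUE
  map$degenerate <- FALSE
  map
}

#' Normalized sum-of-squared-difference between two maps
#'
#' Map-contrast statistic in percent between two max-normalized maps
#' A and B:
#' \deqn{SSD = 100 \cdot \frac{\sum_{ij} (nRMS_A - nRMS_B)^2}
#'       {\sum_{ij} (nRMS_A^2 + nRMS_B^2)}.}
#' Identical maps give 0; maps with disjoint support (no channel active in
#' both) give exactly 100, because the cross term
#' \eqn{\sum nRMS_A \, nRMS_B} vanishes.  For non-negative maps the value
#' always lies in `[0, 100]` and it is symmetric in its arguments.
#'
#' The denominator is isolated in `ssd_denominator` so alternative
#' normalizations can be swapped in and compared; `"sum_of_squares"`
#' (default) is the unique simple quadratic choice consistent with both
#' anchor behaviours (identical gives 0, disjoint gives 100).
#'
#' @param a,b Max-normalized, non-degenerate `rms_map`s of equal shape
#'   (see [normalize_map()]); un-normalized maps are normalized on the fly.
#' @param denominator Denominator variant; only `"sum_of_squares"` is
#'   currently implemented.
#' @return Object of class `ssd_result`: list with `ssd_percent` and
#'   `condition_pair`.
#' @export
map_ssd <- function(a, b, denominator = c("sum_of_squares")) {
  stopifnot(inherits(a, "rms_map"), inherits(b, "rms_map"))
  denominator <- match.arg(denominator)
  if (!all(dim(a$values) == dim(b$values))) {
    stop("maps have mismatched shapes", call. = FALSE)
  }
  if (!isTRUE(a$normalized)) a <- normalize_map(a)
  if (!isTRUE(b$normalized)) b <- normalize_map(b)
  if (isTRUE(a$degenerate) || isTRUE(b$degenerate)) {
    stop("degenerate (all-zero) map: SSD undefined", call. = FALSE)
  }
  num <- sum((a$values - b$values)^2)
  den <- ssd_denominator(a$values, b$values, denominator)
  structure(
    list(ssd_percent = 100 * num / den,
         condition_pair = c(a$condition, b$condition),
         denominator = denominator),
    class = "ssd_result"
  )
}

ssd_denominator <- function(na, nb, variant = "sum_of_squares") {
  switch(variant,
         sum_of_squares = sum(na^2 + nb^2),
         stop("unknown SSD denominator variant: ", variant, call. = FALSE))
}

#' @export
print.ssd_result <- function(x, ...) {
  cat(sprintf("SSD = %.3f%% (%s vs %s)\n", x$ssd_percent,
              x$condition_pair[1], x$condition_pair[2]))
  invisible(x)
}

#' Upsample a map for display (bilinear)
#'
#' Linearly interpolates the map on its relative-coordinate lattice by an
#' integer factor per axis (tensor-product linear interpolation), for
#' visual presentation only.  The original lattice points are reproduced
#' exactly.  This function is never used by [map_centroid()] or
#' [map_ssd()], which operate on the original un-interpolated grid.
#'
#' @param map An `rms_map`.
#' @param factor Integer upsampling factor per axis (default 6).
#' @return Dense numeric matrix of size
#'   `((n_rows - 1) * factor + 1) x ((n_cols - 1) * factor + 1)`.
#' @export
interpolate_for_display <- function(map, factor = 6L) {
  stopifnot(inherits(map, "rms_map"))
  factor <- as.integer(factor)
  if (factor < 1) stop("`factor` must be >= 1", call. = FALSE)
  v <- map$values
  if (factor == 1L) return(v)
  nr <- nrow(v); nc <- ncol(v)
  ri <- seq(1, nr, by = 1 / factor)
  ci <- seq(1, nc, by = 1 / factor)
  # interpolate along rows, then along columns
  tmp <- apply(v, 2, function(col) stats::approx(seq_len(nr), col, ri)$y)
  t(apply(tmp, 1, function(row) stats::approx(seq_len(nc), row, ci)$y))
}

#' Write / read a map as delimited text
#'
#' Tab-separated matrix with `#`-prefixed header comments recording the
#' grid configuration, condition label and normalization state.
#'
#' @param map An `rms_map`.
#' @param path File path.
#' @return `write_map` invisibly returns `path`; `read_map` returns an
#'   `rms_map`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "rms_map"))
  g <- map$grid
  hdr <- c(
    sprintf("# grid: %d x %d span [%g, %g]", g$n_rows, g$n_cols,
            g$col_span_percent[1], g$col_span_percent[2]),
    sprintf("# condition: %s", map$condition),
    sprintf("# normalized: %s", isTRUE(map$normalized))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(map$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  gi <- as.numeric(regmatches(hdr[1],
        gregexpr("-?[0-9.]+", hdr[1]))[[1]])
  cond <- sub("^# condition: ", "", hdr[2])
  normed <- identical(sub("^# normalized: ", "", hdr[3]), "TRUE")
  body <- lines[!grepl("^#", lines)]
  m <- as.matrix(utils::read.table(text = body, sep = "\t"))
  grid <- build_grid(gi[1], gi[2], c(gi[3], gi[4]))
  out <- build_map(as.numeric(t(m)), grid, condition = cond)
  out$normalized <- normed
  if (normed) out$degenerate <- max(out$values) == 0
  out
}
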
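#' Electrode grid geometry for a HD-MEA chip
#'
#' Builds the rectangular electrode layout of a CMOS high-density
#' microelectrode array. Channels are numbered 0-based in row-major order
#' (`channel = row * n_cols + col`), matching the on-disk convention used
#' throughout the package. The default chip is a 64 x 64 grid at 42 um pitch
#' (4,096 electrodes, ~7 mm^2 sensing area).
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param pitch electrode pitch in micrometres (> 0).
#' @param readout_group optional integer vector, one entry per channel,
#'   identifying channels that share pre-amplification wiring. Defaults to
#'   the column index, a proxy for column-parallel readout on CMOS chips.
#' @return An object of class `mea_geometry`: a list with `n_rows`,
#'   `n_cols`, `pitch`, `positions` (channels x 2 matrix of x/y in um, row
#'   major) and `readout_group`.
#' @examples
#' g <- make_geometry(2, 2, 10)
#' g$positions   # (0,0), (10,0), (0,10), (10,10)
#' @export
make_geometry <- function(n_rows = 64L, n_cols = 64L, pitch = 42,
                          readout_group = NULL) {
  if (!is.numeric(n_rows) || length(n_rows) != 1L || n_rows < 1 ||
      n_rows != round(n_rows))
    stop("n_rows must be a positive integer")
  if (!is.numeric(n_cols) || length(n_cols) != 1L || n_cols < 1 ||
      n_cols != round(n_cols))
    stop("n_cols must be a positive integer")
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0)
    stop("pitch must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_ch <- n_rows * n_cols
  ch <- seq_len(n_ch) - 1L
  row <- ch %/% n_cols
  col <- ch %% n_cols
  positions <- cbind(x = col * pitch, y = row * pitch)
  if (is.null(readout_group)) {
    readout_group <- col
  } else {
    if (length(readout_group) != n_ch)
      stop("readout_group must have one entry per channel")
    readout_group <- as.integer(readout_group)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
         positions = positions, readout_group = readout_group),
    class = "mea_geometry")
}

#' @export
print.mea_geometry <- function(x, ...) {
  cat(sprintf("mea_geometry: %d x %d grid, pitch %g um, %d channels\n",
              x$n_rows, x$n_cols, x$pitch, n_channels(x)))
  invisible(x)
}

#' Number of channels of a geometry or recording
#' @param x an `mea_geometry` or `mea_recording`.
#' @return integer channel count.
#' @export
n_channels <- function(x) {
  if (inherits(x, "mea_recording")) return(nrow(x$voltages))
  x$n_rows * x$n_cols
}

#' Channel index to (row, col) and back
#'
#' Channels are 0-based, row-major: `channel = row * n_cols + col`.
#'
#' @param channel 0-based channel indices.
#' @param geometry an `mea_geometry`.
#' @return `chan_to_rowcol`: 2-column matrix of 0-based (row, col);
#'   `rowcol_to_chan`: 0-based channel indices.
#' @export
chan_to_rowcol <- function(channel, geometry) {
  stopifnot(all(channel >= 0), all(channel < n_channels(geometry)))
  cbind(row = channel %/% geometry$n_cols, col = channel %% geometry$n_cols)
}

#' @rdname chan_to_rowcol
#' @param row,col 0-based grid coordinates.
#' @export
rowcol_to_chan <- function(row, col, geometry) {
  stopifnot(all(row >= 0), all(row < geometry$n_rows),
            all(col >= 0), all(col < geometry$n_cols))
  as.integer(row * geometry$n_cols + col)
}

validate_geometry <- function(g) {
  stopifnot(inherits(g, "mea_geometry"))
  n_ch <- g$n_rows * g$n_cols
  if (nrow(g$positions) != n_ch)
    stop("geometry: positions must have n_rows*n_cols rows")
  if (anyDuplicated(g$positions))
    stop("geometry: electrode positions must be unique")
  if (g$pitch <= 0) stop("geometry: pitch must be > 0")
  if (length(g$readout_group) != n_ch)
    stop("geometry: readout_group length mismatch")
  invisible(g)
}
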
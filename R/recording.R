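#' Multichannel extracellular recording container
#'
#' A recording is a channels x samples voltage matrix in microvolts plus its
#' sampling rate, electrode geometry and start time. Matrix row `i` holds
#' channel `i - 1` (channels are 0-based, row-major over the grid).
#'
#' Voltages are quantized to 32-bit float precision on construction so that
#' in-memory values match the on-disk representation exactly and file
#' round-trips are bit-exact.
#'
#' @param voltages numeric matrix [channel x sample], microvolts. All values
#'   must be finite.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param geometry an [make_geometry()] object whose channel count equals
#'   `nrow(voltages)`.
#' @param t0 recording start time in seconds (default 0).
#' @param quantize quantize voltages to float32 (default TRUE).
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(voltages, sampling_rate, geometry, t0 = 0,
                          quantize = TRUE) {
  if (!is.matrix(voltages)) stop("voltages must be a matrix")
  if (quantize) voltages <- float32_quantize(voltages)
  rec <- structure(
    list(voltages = voltages, sampling_rate = sampling_rate,
         geometry = geometry, t0 = t0),
    class = "mea_recording")
  validate_recording(rec)
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "mea_recording"))
  validate_geometry(rec$geometry)
  if (!is.numeric(rec$sampling_rate) || length(rec$sampling_rate) != 1L ||
      rec$sampling_rate <= 0)
    stop("sampling_rate must be a single value > 0")
  if (nrow(rec$voltages) != n_channels(rec$geometry))
    stop(sprintf("voltage matrix has %d rows but geometry has %d channels",
                 nrow(rec$voltages), n_channels(rec$geometry)))
  if (anyNA(rec$voltages) || !all(is.finite(rec$voltages)))
    stop("voltages must be finite (NaN/Inf forbidden)")
  invisible(rec)
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "mea_recording: %d channels x %d samples (%.3f s @ %g Hz), t0 = %g s\n",
    nrow(x$voltages), ncol(x$voltages),
    ncol(x$voltages) / x$sampling_rate, x$sampling_rate, x$t0))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `mea_recording`.
#' @export
rec_duration <- function(rec) ncol(rec$voltages) / rec$sampling_rate

# Round doubles to the nearest IEEE float32, keeping double storage.
float32_quantize <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
               what = "numeric", size = 4L, n = length(x))
  dim(y) <- d
  y
}

#' Read / write a recording in the package HDF5 layout
#'
#' Layout: datasets `/voltages` (channel x sample, float32, uV),
#' `/sampling_rate` (scalar Hz), `/geometry/positions` (channel x 2, um),
#' `/geometry/readout_group` (per channel), and root attributes `n_rows`,
#' `n_cols`, `pitch_um`, `t0_s`.
#'
#' @param path file path.
#' @return `read_recording`: an `mea_recording`; `write_recording`:
#'   the path, invisibly.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  contents <- rhdf5::h5ls(path)$name
  for (need in c("voltages", "sampling_rate", "positions")) {
    if (!need %in% contents)
      stop(sprintf("%s: missing dataset '%s'", path, need))
  }
  att <- rhdf5::h5readAttributes(path, "/")
  for (need in c("n_rows", "n_cols", "pitch_um", "t0_s")) {
    if (is.null(att[[need]]))
      stop(sprintf("%s: missing root attribute '%s'", path, need))
  }
  voltages <- rhdf5::h5read(path, "voltages")
  sr <- as.numeric(rhdf5::h5read(path, "sampling_rate"))
  rg <- if ("readout_group" %in% contents)
    as.integer(rhdf5::h5read(path, "geometry/readout_group")) else NULL
  geom <- make_geometry(as.integer(att$n_rows), as.integer(att$n_cols),
                        as.numeric(att$pitch_um), readout_group = rg)
  pos <- rhdf5::h5read(path, "geometry/positions")
  if (nrow(voltages) != n_channels(geom))
    stop(sprintf(
      "%s: /voltages has %d channels but geometry declares %d",
      path, nrow(voltages), n_channels(geom)))
  if (!isTRUE(all.equal(unname(pos), unname(geom$positions),
                        tolerance = 1e-6)))
    stop(sprintf("%s: stored positions do not match a regular grid", path))
  mea_recording(voltages, sr, geom, t0 = as.numeric(att$t0_s),
                quantize = FALSE)
}

#' @rdname read_recording
#' @param rec an `mea_recording` (validated before any write).
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(path, "voltages", dims = dim(rec$voltages),
                         H5type = "H5T_IEEE_F32LE",
                         chunk = c(nrow(rec$voltages),
                                   min(ncol(rec$voltages), 16384L)))
  rhdf5::h5write(rec$voltages, path, "voltages")
  rhdf5::h5write(rec$sampling_rate, path, "sampling_rate")
  rhdf5::h5createGroup(path, "geometry")
  rhdf5::h5write(rec$geometry$positions, path, "geometry/positions")
  rhdf5::h5write(as.integer(rec$geometry$readout_group), path,
                 "geometry/readout_group")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(rec$geometry$n_rows, fid, "n_rows")
  rhdf5::h5writeAttribute(rec$geometry$n_cols, fid, "n_cols")
  rhdf5::h5writeAttribute(rec$geometry$pitch, fid, "pitch_um")
  rhdf5::h5writeAttribute(rec$t0, fid, "t0_s")
  invisible(path)
}

#' Read / write a per-channel region-label map
#'
#' CSV with columns `channel` (0-based) and `region`. Channels absent from
#' the file are labelled `"UNASSIGNED"`. Region labels stand in for
#' structural clusters (e.g. hippocampal DG/CA1/CA3 or olfactory-bulb
#' GL/EPL/GCL layers) identified by optical imaging.
#'
#' @param path CSV path.
#' @param n_channels total channel count of the recording.
#' @return character vector of length `n_channels`.
#' @export
read_region_map <- function(path, n_channels) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "region") %in% names(df)))
    stop("region map must have columns channel, region")
  if (any(df$channel < 0 | df$channel >= n_channels))
    stop("region map: channel index out of range")
  out <- rep("UNASSIGNED", n_channels)
  out[df$channel + 1L] <- df$region
  out
}

#' @rdname read_region_map
#' @param regions character vector of per-channel labels.
#' @export
write_region_map <- function(regions, path) {
  utils::write.csv(
    data.frame(channel = seq_along(regions) - 1L, region = regions),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
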
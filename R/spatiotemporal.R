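#' Bin events into a spatiotemporal frame stack
#'
#' Produces topographical activity maps: a `[bin, row, col]` array where
#' each frame holds, per electrode, the number (or summed amplitude) of
#' events whose peak time falls in that time bin. Total activity is
#' conserved exactly.
#'
#' @param events an `mea_events`.
#' @param geometry the grid `mea_geometry`.
#' @param bin_width bin width in seconds (50 ms for LFP, 10 ms for spikes
#'   by convention).
#' @param weight `"COUNT"` or `"AMPLITUDE"`.
#' @param t_start,t_end time span covered (defaults: 0 to the last event).
#' @return a `frame_stack`: list with `frames` (array bin x row x col),
#'   `bin_width`, `t_start`.
#' @export
bin_events <- function(events, geometry, bin_width = 0.05,
                       weight = c("COUNT", "AMPLITUDE"),
                       t_start = 0, t_end = NULL) {
  weight <- match.arg(weight)
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(t_end))
    t_end <- if (nrow(events)) max(events$t_peak) + 1e-9 else bin_width
  n_bins <- max(1L, ceiling((t_end - t_start) / bin_width))
  fr <- array(0, dim = c(n_bins, geometry$n_rows, geometry$n_cols))
  if (nrow(events)) {
    b <- floor((events$t_peak - t_start) / bin_width) + 1L
    ok <- b >= 1L & b <= n_bins
    rc <- chan_to_rowcol(events$channel, geometry)
    w <- if (weight == "COUNT") rep(1, nrow(events)) else events$amplitude_uv
    for (i in which(ok))
      fr[b[i], rc[i, 1L] + 1L, rc[i, 2L] + 1L] <-
        fr[b[i], rc[i, 1L] + 1L, rc[i, 2L] + 1L] + w[i]
  }
  structure(list(frames = fr, bin_width = bin_width, t_start = t_start),
            class = "frame_stack")
}

#' Center-of-activity trajectory (CAT)
#'
#' Per frame, the activity-weighted centroid of electrode positions:
#' `sum(a_i * p_i) / sum(a_i)` over electrodes `i`. Frames with zero
#' activity yield no point. CATs trace the propagation of activity across
#' the array.
#'
#' @param stack a [bin_events()] frame stack.
#' @param geometry the grid `mea_geometry` used to build the stack.
#' @return data.frame `t` (bin midpoint, s), `x_um`, `y_um`,
#'   `total_activity`.
#' @export
compute_cat <- function(stack, geometry) {
  nb <- dim(stack$frames)[1L]
  px <- matrix(geometry$positions[, 1L], geometry$n_rows, geometry$n_cols,
               byrow = TRUE)
  py <- matrix(geometry$positions[, 2L], geometry$n_rows, geometry$n_cols,
               byrow = TRUE)
  pts <- lapply(seq_len(nb), function(b) {
    a <- stack$frames[b, , ]
    tot <- sum(a)
    if (tot <= 0) return(NULL)
    data.frame(t = stack$t_start + (b - 0.5) * stack$bin_width,
               x_um = sum(a * px) / tot, y_um = sum(a * py) / tot,
               total_activity = tot)
  })
  out <- do.call(rbind, pts)
  if (is.null(out))
    out <- data.frame(t = numeric(), x_um = numeric(), y_um = numeric(),
                      total_activity = numeric())
  out
}

#' Direction of a CAT by least squares
#'
#' Fits x(t) and y(t) linearly over the trajectory points and returns the
#' propagation direction of the fitted velocity vector.
#'
#' @param cat_points data.frame from [compute_cat()] with >= 2 points.
#' @return list with `angle_deg` (counterclockwise from +x) and
#'   `speed_um_s`.
#' @export
cat_direction <- function(cat_points) {
  if (nrow(cat_points) < 2L) stop("need at least 2 CAT points")
  vx <- stats::coef(stats::lm(x_um ~ t, cat_points))[2L]
  vy <- stats::coef(stats::lm(y_um ~ t, cat_points))[2L]
  list(angle_deg = atan2(vy, vx) * 180 / pi,
       speed_um_s = unname(sqrt(vx^2 + vy^2)))
}

#' Per-region event incidence
#'
#' @param events an `mea_events`.
#' @param region_map character vector of per-channel region labels.
#' @param duration recording duration (s), > 0.
#' @return data.frame per region: `n_channels`, `n_events`,
#'   `rate_per_electrode` (events/s per electrode) and `share` of all
#'   events (shares sum to 1 when any events exist).
#' @export
event_incidence <- function(events, region_map, duration) {
  if (duration <= 0) stop("duration must be > 0")
  regions <- sort(unique(region_map))
  total <- nrow(events)
  out <- lapply(regions, function(r) {
    ch <- which(region_map == r) - 1L
    n_ev <- sum(events$channel %in% ch)
    data.frame(region = r, n_channels = length(ch), n_events = n_ev,
               rate_per_electrode = n_ev / (length(ch) * duration),
               share = if (total > 0) n_ev / total else 0)
  })
  do.call(rbind, out)
}
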
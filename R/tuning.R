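# Per-neuron tuning summaries: spatial rate maps, speed and direction
# tuning curves.

#' Spatial tuning map of one neuron
#'
#' Computes an occupancy-normalized event-rate map on a fine raster
#' (default 1-cm pixels) and smooths it with a Gaussian kernel of width
#' `sigma` cm (default 2.0, the display smoothing used for these maps).
#' Smoothing is occupancy-weighted and mass-conserving: event counts and
#' occupancy are smoothed with the same truncated kernel, renormalized at
#' the arena edges so every source pixel keeps its full mass inside the
#' arena, and then divided. This preserves both the total event count and
#' the occupancy-weighted mean rate exactly. The map is normalized to the
#' neuron's maximum rate.
#'
#' @param events binary event vector (one value per frame) or a
#'   `population_recording` plus `neuron`.
#' @param trajectory the aligned `trajectory`.
#' @param sigma Gaussian smoothing width in cm (0 = no smoothing).
#' @param pixel_cm raster pixel size in cm.
#' @param neuron neuron index or id when `events` is a recording.
#' @return a `spatial_tuning_map`: list with matrices `rate` (events/s),
#'   `occupancy` (s), `normalized` (peak 1; all zero when the neuron
#'   never fired, flagged by `no_events`), and `sigma`, `pixel_cm`.
#' @export
spatial_tuning_map <- function(events, trajectory, sigma = 2.0,
                               pixel_cm = 1, neuron = 1L) {
  events <- as_event_vector(events, neuron)
  stopifnot(inherits(trajectory, "trajectory"))
  if (length(events) != n_frames(trajectory)) {
    stop("events and trajectory differ in frame count")
  }
  if (sigma < 0) stop("sigma must be nonnegative")
  arena <- trajectory$arena
  ncol_px <- max(2L, ceiling(arena[1] / pixel_cm))
  nrow_px <- max(2L, ceiling(arena[2] / pixel_cm))
  dt <- 1 / trajectory$frame_rate

  col <- pmin(floor(trajectory$x_cm / (arena[1] / ncol_px)), ncol_px - 1L) + 1L
  row <- pmin(floor(trajectory$y_cm / (arena[2] / nrow_px)), nrow_px - 1L) + 1L
  idx <- (col - 1L) * nrow_px + row
  occ <- matrix(tabulate(idx, nrow_px * ncol_px) * dt, nrow_px, ncol_px)
  if (sum(occ) <= 0) stop("zero total occupancy")
  cnt <- matrix(tabulate(idx[events == 1L], nrow_px * ncol_px),
                nrow_px, ncol_px)

  if (sigma > 0) {
    cnt <- smooth_grid(cnt, sigma, pixel_cm)
    occ_s <- smooth_grid(occ, sigma, pixel_cm)
  } else {
    occ_s <- occ
  }
  rate <- ifelse(occ_s > 0, cnt / occ_s, 0)
  peak <- max(rate)
  normalized <- if (peak > 0) rate / peak else rate

  structure(list(rate = rate, occupancy = occ_s, raw_occupancy = occ,
                 normalized = normalized, sigma = sigma,
                 pixel_cm = pixel_cm, no_events = peak == 0),
            class = "spatial_tuning_map")
}

# Mass-conserving separable Gaussian smoothing, truncated at 3 sigma,
# with per-source renormalization at the grid edges: out = K (g / K 1),
# so column sums of the effective operator are 1 and sum(out) == sum(g).
smooth_grid <- function(g, sigma_cm, pixel_cm) {
  sd_px <- sigma_cm / pixel_cm
  half <- max(1L, ceiling(3 * sd_px))
  k <- exp(-(seq(-half, half))^2 / (2 * sd_px^2))
  conv1 <- function(m, along_rows) {
    if (!along_rows) m <- t(m)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq(-half, half)) {
      w <- k[o + half + 1L]
      src <- seq_len(n) - o
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + w * m[src[ok], , drop = FALSE]
    }
    if (!along_rows) t(out) else out
  }
  ones <- matrix(1, nrow(g), ncol(g))
  mass <- conv1(conv1(ones, TRUE), FALSE)
  conv1(conv1(g / mass, TRUE), FALSE)
}

as_event_vector <- function(events, neuron = 1L) {
  if (inherits(events, "population_recording")) {
    events <- events$events[, neuron]
  }
  ev <- as.integer(events)
  if (any(is.na(ev)) || any(ev != 0L & ev != 1L)) {
    stop("event train must be binary 0/1")
  }
  ev
}

#' Speed tuning curve of one neuron
#'
#' Mean event rate (events/s) in each of the three speed classes
#' (0-1, 1-5, >5 cm/s). Classes never visited are flagged undefined.
#'
#' @param events binary event vector or `population_recording`.
#' @param state output of [discretize_states()].
#' @param frame_rate frames per second (used to convert counts to rates).
#' @param neuron neuron index/id when `events` is a recording.
#' @return a `speed_tuning_curve`: list with `rate` (length 3),
#'   `time_s`, `count`, `undefined`.
#' @export
speed_tuning_curve <- function(events, state, frame_rate = 3, neuron = 1L) {
  if (inherits(events, "population_recording")) frame_rate <- events$frame_rate
  events <- as_event_vector(events, neuron)
  curve_by_class(events, state$speed_class, 3L, frame_rate,
                 class_out = "speed_tuning_curve")
}

#' Direction tuning curve of one neuron
#'
#' Mean event rate in each of the 8 motion-direction bins (bin 1 = north,
#' increasing toward west), plus a max-normalized variant. Frames without
#' a defined direction are excluded.
#'
#' @inheritParams speed_tuning_curve
#' @return a `direction_tuning_curve`: list with `rate` (length 8),
#'   `normalized`, `time_s`, `count`, `undefined`.
#' @export
direction_tuning_curve <- function(events, state, frame_rate = 3,
                                   neuron = 1L) {
  if (inherits(events, "population_recording")) frame_rate <- events$frame_rate
  events <- as_event_vector(events, neuron)
  out <- curve_by_class(events, state$direction_bin, 8L, frame_rate,
                        class_out = "direction_tuning_curve")
  peak <- max(out$rate, na.rm = TRUE)
  out$normalized <- if (is.finite(peak) && peak > 0) out$rate / peak else out$rate
  out
}

curve_by_class <- function(events, labels, n_classes, frame_rate, class_out) {
  if (length(events) != length(labels)) {
    stop("events and state labels differ in length")
  }
  ok <- !is.na(labels)
  cnt <- tabulate(labels[ok & events == 1L], n_classes)
  occ <- tabulate(labels[ok], n_classes) / frame_rate
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  structure(list(rate = rate, time_s = occ, count = cnt,
                 undefined = occ == 0),
            class = class_out)
}
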
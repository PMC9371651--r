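# Inhomogeneous-Poisson calcium-event simulation.
#
# Events are generated by per-frame Bernoulli thinning: at frame t the
# event probability is rate_t * dt (clipped to [0, 1] with a warning if
# clipping occurs), where rate_t is the product of a baseline and
# mean-one modulation factors for position, speed and direction. Output
# trains are binarized, matching the 3-Hz event trains the analysis
# consumes.

#' Generate a synthetic population recording for an open-field session
#'
#' Per-neuron event rate at frame t:
#' \deqn{rate_t = baseline \times f_{place}(x_t, y_t) \times
#'   f_{speed}(v_t) \times f_{dir}(\theta_t)}
#' where the place factor mixes a flat component with a Gaussian bump
#' normalized to unit mean over the arena, the speed factor is a linear
#' ramp `1 + slope * (v - mean(v))` floored at 0, and the direction factor
#' is a von Mises density normalized by its circular mean
#' (`exp(kappa*cos(theta - pref)) / I0(kappa)`). All three factors have
#' mean ~1 over the session, so the realized mean event rate tracks
#' `baseline_rate`.
#'
#' @param trajectory a [simulate_of_trajectory()] object.
#' @param spec a [make_tuning_spec()] object.
#' @param seed integer seed; output is deterministic given it.
#' @return a `population_recording`: list with binary `events` matrix
#'   (frames x neurons), `neuron_ids`, `frame_rate`.
#' @export
generate_events <- function(trajectory, spec, seed = 1L) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (!is.data.frame(spec) || nrow(spec) == 0L) {
    stop("spec must be a nonempty tuning_spec")
  }
  n <- n_frames(trajectory)
  dt <- 1 / trajectory$frame_rate
  kin <- compute_kinematics(trajectory)
  v <- kin$speed
  vbar <- mean(v)
  theta <- kin$direction
  ok_dir <- kin$valid_direction
  arena <- trajectory$arena
  area <- arena[1] * arena[2]

  set.seed(as.integer(seed))
  events <- matrix(0L, n, nrow(spec))
  clipped <- 0L
  for (j in seq_len(nrow(spec))) {
    s <- spec[j, ]
    rate <- rep(s$baseline_rate, n)

    g <- min(max(s$place_gain, 0), 1)
    if (g > 0 && s$place_width > 0) {
      w <- s$place_width
      bump <- exp(-((trajectory$x_cm - s$place_cx)^2 +
                    (trajectory$y_cm - s$place_cy)^2) / (2 * w^2))
      # mean of the bump over a uniform arena (edge-truncated Gaussian)
      px <- stats::pnorm((arena[1] - s$place_cx) / w) -
            stats::pnorm(-s$place_cx / w)
      py <- stats::pnorm((arena[2] - s$place_cy) / w) -
            stats::pnorm(-s$place_cy / w)
      mean_bump <- 2 * pi * w^2 * px * py / area
      rate <- rate * ((1 - g) + g * bump / mean_bump)
    }

    if (s$speed_slope != 0) {
      rate <- rate * pmax(0, 1 + s$speed_slope * (v - vbar))
    }

    if (s$direction_kappa > 0) {
      f_dir <- exp(s$direction_kappa * cos(theta - s$direction_pref)) /
        besselI(s$direction_kappa, 0)
      f_dir[!ok_dir] <- 1
      rate <- rate * f_dir
    }

    p <- rate * dt
    over <- p > 1
    if (any(over)) {
      clipped <- clipped + sum(over)
      p[over] <- 1
    }
    events[, j] <- stats::rbinom(n, 1L, p)
  }
  if (clipped > 0L) {
    warning(sprintf(
      "event probability exceeded 1 at %d frame(s); clipped to 1", clipped))
  }

  new_population_recording(events, spec$neuron_id, trajectory$frame_rate)
}

new_population_recording <- function(events, neuron_ids, frame_rate) {
  storage.mode(events) <- "integer"
  colnames(events) <- neuron_ids
  structure(list(events = events,
                 neuron_ids = as.character(neuron_ids),
                 frame_rate = frame_rate),
            class = "population_recording")
}

#' @export
print.population_recording <- function(x, ...) {
  cat(sprintf(
    "<population_recording> %d neurons x %d frames @ %.3g Hz, mean rate %.4f Hz\n",
    ncol(x$events), nrow(x$events), x$frame_rate,
    mean(x$events) * x$frame_rate))
  invisible(x)
}

#' Mean event rate of a recording
#'
#' Total events divided by total neuron-time, in events/s.
#'
#' @param recording a `population_recording`.
#' @return scalar rate (Hz).
#' @export
mean_event_rate <- function(recording) {
  sum(recording$events) /
    (nrow(recording$events) * ncol(recording$events) / recording$frame_rate)
}
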
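# Open-field trajectory simulation.
#
# The motion model is an Ornstein-Uhlenbeck speed process coupled to a
# diffusing heading, integrated at the imaging frame rate with reflecting
# arena walls. It is deliberately simple: what downstream analyses need is
# a bounded, smooth 2-D track whose speed distribution covers the three
# behavioural speed classes (0-1, 1-5, >5 cm/s) and whose occupancy fills
# the arena within a 30-min session.

#' Motion-model parameters for the open-field simulator
#'
#' @param mean_speed long-run mean running speed (cm/s).
#' @param speed_sd stationary standard deviation of the speed process (cm/s).
#' @param speed_tau relaxation time of the speed process (s).
#' @param heading_sd heading diffusion rate (rad per sqrt(s)).
#' @return a list of class `of_motion_params`.
#' @export
of_motion_params <- function(mean_speed = 5, speed_sd = 4,
                             speed_tau = 2, heading_sd = 1.2) {
  if (mean_speed < 0 || speed_sd < 0 || speed_tau <= 0 || heading_sd < 0) {
    stop("motion parameters must be nonnegative (speed_tau strictly positive)")
  }
  structure(list(mean_speed = mean_speed, speed_sd = speed_sd,
                 speed_tau = speed_tau, heading_sd = heading_sd),
            class = "of_motion_params")
}

#' Simulate an open-field trajectory
#'
#' Generates a 2-D position track at a fixed frame rate (default 3 Hz, the
#' miniscope imaging rate) inside a rectangular arena with reflecting walls.
#' Speed follows an Ornstein-Uhlenbeck process floored at zero; heading
#' diffuses. With `mean_speed = 0` and `speed_sd = 0` the animal stays put.
#'
#' @param duration_s session length in seconds (default 1800, a 30-min
#'   session).
#' @param frame_rate sampling rate in Hz (default 3).
#' @param arena `c(width, height)` of the arena in cm (default 40 x 40).
#' @param motion an [of_motion_params()] list.
#' @param seed integer seed; the trajectory is deterministic given it.
#' @return an object of class `trajectory`: list with `time_s`, `x_cm`,
#'   `y_cm`, `frame_rate`, `arena`, `duration_s`.
#' @export
simulate_of_trajectory <- function(duration_s = 1800, frame_rate = 3,
                                   arena = c(40, 40),
                                   motion = of_motion_params(),
                                   seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (length(arena) != 2L || any(arena <= 0)) {
    stop("arena must be two positive side lengths (cm)")
  }
  n <- as.integer(round(duration_s * frame_rate))
  if (n < 2L) stop("session too short: fewer than 2 frames")
  dt <- 1 / frame_rate

  set.seed(as.integer(seed))
  sp <- numeric(n)
  hd <- numeric(n)
  x <- numeric(n)
  y <- numeric(n)
  sp[1] <- max(0, stats::rnorm(1, motion$mean_speed, motion$speed_sd))
  hd[1] <- stats::runif(1, -pi, pi)
  x[1] <- stats::runif(1, 0.25, 0.75) * arena[1]
  y[1] <- stats::runif(1, 0.25, 0.75) * arena[2]

  # OU pull toward mean_speed; diffusion scaled for stationary sd speed_sd.
  k_sp <- dt / motion$speed_tau
  s_sp <- motion$speed_sd * sqrt(2 * dt / motion$speed_tau)
  eps_sp <- stats::rnorm(n)
  eps_hd <- stats::rnorm(n)
  for (t in 2:n) {
    s <- sp[t - 1] + (motion$mean_speed - sp[t - 1]) * k_sp + s_sp * eps_sp[t]
    sp[t] <- max(0, s)
    h <- hd[t - 1] + motion$heading_sd * sqrt(dt) * eps_hd[t]
    # heading 0 = north (+y), positive toward west (-x)
    dx <- -sp[t] * dt * sin(h)
    dy <- sp[t] * dt * cos(h)
    xn <- x[t - 1] + dx
    yn <- y[t - 1] + dy
    if (xn < 0) { xn <- -xn; h <- -h }
    if (xn > arena[1]) { xn <- 2 * arena[1] - xn; h <- -h }
    if (yn < 0) { yn <- -yn; h <- pi - h }
    if (yn > arena[2]) { yn <- 2 * arena[2] - yn; h <- pi - h }
    # clamp guards pathological double reflections at huge speeds
    x[t] <- min(max(xn, 0), arena[1])
    y[t] <- min(max(yn, 0), arena[2])
    hd[t] <- wrap_angle(h)
  }

  structure(list(time_s = (seq_len(n) - 1) * dt,
                 x_cm = x, y_cm = y,
                 frame_rate = frame_rate,
                 arena = as.numeric(arena),
                 duration_s = duration_s),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames @ %.3g Hz (%.0f s), arena %g x %g cm\n",
              length(x$time_s), x$frame_rate, x$duration_s,
              x$arena[1], x$arena[2]))
  invisible(x)
}

n_frames <- function(trajectory) length(trajectory$time_s)
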
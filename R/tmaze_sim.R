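# Forced-alternation T-maze simulation.
#
# Each trial is a forced-choice run (the animal is forced into a randomly
# chosen open arm) followed by a free-choice run; the trial is correct
# when the free choice is the arm opposite the forced one. Behaviour is
# emulated at the trial level (forced side uniform; free choice correct
# with probability `correct_rate`, default the observed 71.4%), and
# left/right-tuned neurons modulate their event rate inside the
# forced-arm window (0..+5 s after the forced turn, labelled by the
# current arm) and/or the decision window (-6..-1 s before the
# free-choice turn, labelled by the future chosen side).

#' Timing parameters for a simulated T-maze session
#'
#' @param trial_duration_s duration of one trial (s).
#' @param forced_turn_s nominal time of the forced turn within a trial (s).
#' @param free_choice_turn_s nominal time of the free-choice turn (s).
#' @param jitter_s uniform jitter applied to each turn time (s).
#' @return a list of class `tmaze_timing`.
#' @export
tmaze_timing <- function(trial_duration_s = 30, forced_turn_s = 8,
                         free_choice_turn_s = 22, jitter_s = 1) {
  t <- list(trial_duration_s = trial_duration_s,
            forced_turn_s = forced_turn_s,
            free_choice_turn_s = free_choice_turn_s,
            jitter_s = jitter_s)
  if (forced_turn_s - jitter_s < 0 ||
      forced_turn_s + jitter_s + 5 > trial_duration_s) {
    stop("forced-arm window (0..+5 s after the forced turn) does not fit in the trial")
  }
  if (free_choice_turn_s - jitter_s - 6 < 0 ||
      free_choice_turn_s + jitter_s > trial_duration_s) {
    stop("decision window (-6..-1 s before the free-choice turn) does not fit in the trial")
  }
  structure(t, class = "tmaze_timing")
}

#' Simulate a forced-alternation T-maze session
#'
#' @param n_trials number of trials (default 50, the session length used
#'   with this task).
#' @param correct_rate probability that the free choice alternates from
#'   the forced side (default 0.714, the wild-type performance;
#'   0.5 corresponds to a free choice independent of the forced side).
#' @param timing a [tmaze_timing()] list.
#' @param spec a [make_tuning_spec()] object providing per-neuron LR
#'   preferences (`lr_arm_pref`/`gain`, `lr_decision_pref`/`gain`), or
#'   `NULL` for a behaviour-only session without a recording.
#' @param frame_rate imaging rate in Hz (default 3).
#' @param seed integer seed.
#' @return a `tmaze_session`: list with `trials` data frame (`trial_id`,
#'   `forced_side`, `free_choice`, `correct`, `forced_turn_time_s`,
#'   `free_choice_turn_time_s`), `recording` (or `NULL`), schematic maze
#'   `trajectory`, `timing`, `frame_rate`.
#' @export
simulate_tmaze_session <- function(n_trials = 50, correct_rate = 0.714,
                                   timing = tmaze_timing(), spec = NULL,
                                   frame_rate = 3, seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (correct_rate < 0 || correct_rate > 1) {
    stop("correct_rate must be in [0, 1]")
  }
  stopifnot(inherits(timing, "tmaze_timing"))
  set.seed(as.integer(seed))

  forced <- sample(c("L", "R"), n_trials, replace = TRUE)
  correct <- stats::runif(n_trials) < correct_rate
  free <- ifelse(correct, ifelse(forced == "L", "R", "L"), forced)
  tdur <- timing$trial_duration_s
  jit <- function() stats::runif(n_trials, -timing$jitter_s, timing$jitter_s)
  t0 <- (seq_len(n_trials) - 1) * tdur
  forced_turn <- t0 + timing$forced_turn_s + jit()
  free_turn <- t0 + timing$free_choice_turn_s + jit()

  trials <- data.frame(trial_id = seq_len(n_trials),
                       forced_side = forced,
                       free_choice = free,
                       correct = free != forced,
                       forced_turn_time_s = forced_turn,
                       free_choice_turn_time_s = free_turn,
                       stringsAsFactors = FALSE)

  n <- as.integer(round(n_trials * tdur * frame_rate))
  dt <- 1 / frame_rate
  times <- (seq_len(n) - 1) * dt
  trajectory <- tmaze_trajectory(trials, timing, times)

  recording <- NULL
  if (!is.null(spec)) {
    trial_idx <- pmin(floor(times / tdur) + 1, n_trials)
    in_arm <- times >= forced_turn[trial_idx] &
      times < forced_turn[trial_idx] + 5
    in_dec <- times >= free_turn[trial_idx] - 6 &
      times < free_turn[trial_idx] - 1
    # side sign: L = +1, R = -1
    arm_sign <- ifelse(forced[trial_idx] == "L", 1, -1)
    dec_sign <- ifelse(free[trial_idx] == "L", 1, -1)

    events <- matrix(0L, n, nrow(spec))
    for (j in seq_len(nrow(spec))) {
      s <- spec[j, ]
      mod <- rep(1, n)
      mod[in_arm] <- 1 + s$lr_arm_gain * s$lr_arm_pref * arm_sign[in_arm]
      mod[in_dec] <- 1 + s$lr_decision_gain * s$lr_decision_pref *
        dec_sign[in_dec]
      p <- pmin(pmax(s$baseline_rate * mod, 0) * dt, 1)
      events[, j] <- stats::rbinom(n, 1L, p)
    }
    recording <- new_population_recording(events, spec$neuron_id, frame_rate)
  }

  structure(list(trials = trials, recording = recording,
                 trajectory = trajectory, timing = timing,
                 frame_rate = frame_rate, n_frames = n),
            class = "tmaze_session")
}

# Schematic maze track: stem from (20, 0) to the junction (20, 40), arms
# to x = 0 (left, west) and x = 40 (right, east). Positions are piecewise
# linear between task landmarks (vectorized over frames); enough
# structure for window extraction and plotting, not a locomotor model.
tmaze_trajectory <- function(trials, timing, times) {
  stem_x <- 20; junc_y <- 40; arm_half <- 20
  n <- length(times)
  tdur <- timing$trial_duration_s
  n_trials <- nrow(trials)
  idx <- pmin(floor(times / tdur) + 1L, n_trials)
  t0 <- (idx - 1) * tdur
  ft <- trials$forced_turn_time_s[idx]
  fc <- trials$free_choice_turn_time_s[idx]
  fx <- ifelse(trials$forced_side[idx] == "L",
               stem_x - arm_half, stem_x + arm_half)
  cx <- ifelse(trials$free_choice[idx] == "L",
               stem_x - arm_half, stem_x + arm_half)
  seg <- function(t, a, b) (t - a) / pmax(b - a, 1e-9)
  t <- times
  x <- rep(stem_x, n)
  y <- numeric(n)
  p1 <- t < ft                               # run up the stem
  y[p1] <- (junc_y * seg(t, t0, ft))[p1]
  p2 <- !p1 & t < ft + 5                     # forced arm
  x[p2] <- (stem_x + (fx - stem_x) * seg(t, ft, ft + 5))[p2]
  y[p2] <- junc_y
  p3 <- !p1 & !p2 & t < fc - 6               # return to start
  u <- seg(t, ft + 5, fc - 6)
  x[p3] <- (fx + (stem_x - fx) * pmin(1, 2 * u))[p3]
  y[p3] <- (junc_y * (1 - pmax(0, 2 * u - 1)))[p3]
  p4 <- !p1 & !p2 & !p3 & t < fc             # approach the junction again
  y[p4] <- (junc_y * seg(t, fc - 6, fc))[p4]
  p5 <- !p1 & !p2 & !p3 & !p4                # chosen arm
  x[p5] <- (stem_x + (cx - stem_x) * pmin(1, seg(t, fc, fc + 5)))[p5]
  y[p5] <- junc_y
  structure(list(time_s = times, x_cm = x, y_cm = y,
                 frame_rate = 1 / (times[2] - times[1]),
                 arena = c(40, 40),
                 duration_s = length(times) * (times[2] - times[1])),
            class = "trajectory")
}

#' @export
print.tmaze_session <- function(x, ...) {
  cat(sprintf(
    "<tmaze_session> %d trials, %.1f%% correct, %s recording\n",
    nrow(x$trials), 100 * mean(x$trials$correct),
    if (is.null(x$recording)) "no" else
      sprintf("%d-neuron", ncol(x$recording$events))))
  invisible(x)
}

#' Correct-choice rate of a T-maze session
#'
#' Percentage of trials where the free choice alternated from the forced
#' side.
#'
#' @param session a `tmaze_session`.
#' @return scalar percentage in \[0, 100\].
#' @export
correct_choice_rate <- function(session) {
  100 * mean(session$trials$correct)
}
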
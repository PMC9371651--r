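# Shared fixtures and independent oracles for the test suite.

# Build a trajectory object directly from coordinates (bypasses the
# simulator so kinematic conventions can be tested on exact paths).
make_traj <- function(x, y, frame_rate = 3, arena = c(40, 40)) {
  structure(list(time_s = (seq_along(x) - 1) / frame_rate,
                 x_cm = as.numeric(x), y_cm = as.numeric(y),
                 frame_rate = frame_rate, arena = as.numeric(arena),
                 duration_s = length(x) / frame_rate),
            class = "trajectory")
}

# Independent brute-force evaluation of the Skaggs information formula
# I = sum_i p_i (lambda_i/lambda) log2(lambda_i/lambda), written directly
# from the per-bin probability/rate definition with an explicit loop.
# Deliberately shares no code with information_content().
skaggs_bruteforce <- function(events, labels, dt, min_occupancy_s = 1) {
  bins <- sort(unique(labels[!is.na(labels)]))
  occ <- sapply(bins, function(b) sum(labels == b, na.rm = TRUE) * dt)
  keep <- occ >= min_occupancy_s
  bins <- bins[keep]; occ <- occ[keep]
  total_t <- sum(occ)
  p <- occ / total_t
  lam <- sapply(seq_along(bins), function(i) {
    sum(events == 1 & labels == bins[i], na.rm = TRUE) / occ[i]
  })
  lbar <- sum(p * lam)
  if (lbar == 0) return(NA_real_)
  acc <- 0
  for (i in seq_along(bins)) {
    if (lam[i] > 0) {
      acc <- acc + p[i] * (lam[i] / lbar) * log2(lam[i] / lbar)
    }
  }
  acc
}

# Random small information-content instance: n_bins state labels over
# enough frames that all bins pass the occupancy threshold, and a sparse
# event train.
random_info_instance <- function(seed) {
  set.seed(seed)
  n_bins <- sample(2:10, 1)
  n <- n_bins * sample(15:60, 1)
  labels <- sample.int(n_bins, n, replace = TRUE)
  n_ev <- sample(1:100, 1)
  events <- integer(n)
  events[sample.int(n, min(n_ev, n))] <- 1L
  list(events = events, labels = labels, dt = 1 / 3)
}

# A tmaze_session with a hand-placed event matrix, for window tests.
manual_tmaze_session <- function(events, trials, frame_rate = 3) {
  rec <- dgcoding:::new_population_recording(
    events, sprintf("n%02d", seq_len(ncol(events))), frame_rate)
  structure(list(trials = trials, recording = rec, trajectory = NULL,
                 timing = tmaze_timing(), frame_rate = frame_rate,
                 n_frames = nrow(events)),
            class = "tmaze_session")
}
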
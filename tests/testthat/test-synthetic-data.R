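test_that("open-field trajectory has the requested frame count and stays in the arena", {
  tr <- simulate_of_trajectory(1800, 3, seed = 7)
  expect_length(tr$time_s, 5400)
  expect_true(all(tr$x_cm >= 0 & tr$x_cm <= 40))
  expect_true(all(tr$y_cm >= 0 & tr$y_cm <= 40))
  expect_equal(diff(tr$time_s), rep(1 / 3, 5399), tolerance = 1e-12)
  # deterministic given seed
  tr2 <- simulate_of_trajectory(1800, 3, seed = 7)
  expect_identical(tr$x_cm, tr2$x_cm)
  expect_error(simulate_of_trajectory(-5), "positive")
  expect_error(simulate_of_trajectory(100, frame_rate = 0), "positive")
})

test_that("zero motion parameters freeze the animal in place", {
  tr <- simulate_of_trajectory(100, 3,
                               motion = of_motion_params(mean_speed = 0,
                                                         speed_sd = 0),
                               seed = 1)
  expect_equal(stats::sd(tr$x_cm), 0)
  expect_equal(stats::sd(tr$y_cm), 0)
  kin <- compute_kinematics(tr)
  expect_true(all(kin$speed == 0))
  expect_true(all(!kin$valid_direction))
})

test_that("default motion covers the arena and all three speed classes", {
  tr <- simulate_of_trajectory(seed = 3)
  kin <- compute_kinematics(tr)
  st <- discretize_states(kin, tr)
  expect_gt(length(unique(st$position_bin)), 80)  # >80% of 10x10 bins
  cls <- table(factor(st$speed_class, levels = 1:3))
  expect_true(all(cls > 0.02 * nrow(st)))  # every class well represented
})

test_that("tuning-spec structures shape the gain correlations as designed", {
  big <- make_tuning_spec(500, "independent", seed = 2)
  expect_lt(abs(cor(big$place_gain, big$speed_slope)), 0.15)
  dep <- make_tuning_spec(70, "dependent", seed = 2)
  expect_gt(cor(dep$place_gain, dep$speed_slope), 0.5)
  exc <- make_tuning_spec(70, "exclusive", seed = 2)
  n_types <- (exc$place_gain > 0) + (exc$speed_slope > 0) +
    (exc$direction_kappa > 0)
  expect_true(all(n_types <= 1))
  one <- make_tuning_spec(1, "independent", seed = 5)
  expect_equal(nrow(one), 1)
  expect_true(one$direction_pref > -pi && one$direction_pref <= pi)
  expect_error(make_tuning_spec(70, "bogus"))
  expect_error(make_tuning_spec(0))
})

test_that("independent structure gives near-zero gain correlation across seeds", {
  rs <- vapply(1:20, function(s) {
    sp <- make_tuning_spec(70, "independent", seed = s)
    abs(cor(sp$place_gain, sp$speed_slope))
  }, numeric(1))
  expect_gte(mean(rs < 0.25), 0.9)
})

test_that("event generation respects degenerate and untuned configurations", {
  tr <- simulate_of_trajectory(600, 3, seed = 1)
  spec <- make_tuning_spec(5, baseline_rate = 0, seed = 1,
                           gain_ranges = list(place = c(0, 0),
                                              speed = c(0, 0),
                                              direction = c(0, 0)))
  rec <- generate_events(tr, spec, seed = 1)
  expect_true(all(rec$events == 0L))
  expect_true(all(rec$events %in% c(0L, 1L)))
})

test_that("untuned neurons at 0.02 Hz produce ~36 events in 1800 s", {
  tr <- simulate_of_trajectory(1800, 3, seed = 2)
  spec <- make_tuning_spec(70, seed = 1, rate_dispersion = 0,
                           gain_ranges = list(place = c(0, 0),
                                              speed = c(0, 0),
                                              direction = c(0, 0)))
  rec <- generate_events(tr, spec, seed = 9)
  counts <- colSums(rec$events)
  # mean of 70 Poisson(36) counts: 36 +/- 3 * sqrt(36/70)
  expect_gt(mean(counts), 36 - 3 * sqrt(36 / 70))
  expect_lt(mean(counts), 36 + 3 * sqrt(36 / 70))
})

test_that("a strong place cell fires almost exclusively inside its field", {
  tr <- simulate_of_trajectory(1800, 3, seed = 4)
  spec <- make_tuning_spec(1, seed = 1)
  spec$place_gain <- 1
  spec$place_width <- 4
  spec$place_cx <- 20
  spec$place_cy <- 20
  spec$speed_slope <- 0
  spec$direction_kappa <- 0
  spec$baseline_rate <- 0.05  # more events for a tighter estimate
  rec <- generate_events(tr, spec, seed = 6)
  ev <- rec$events[, 1] == 1L
  expect_gt(sum(ev), 10)
  in_field <- abs(tr$x_cm[ev] - 20) < 2 * 4 & abs(tr$y_cm[ev] - 20) < 2 * 4
  expect_gt(mean(in_field), 0.9)
})

test_that("event probabilities above 1 are clipped with a warning", {
  tr <- simulate_of_trajectory(60, 3, seed = 1)
  spec <- make_tuning_spec(1, baseline_rate = 10, seed = 1)
  expect_warning(generate_events(tr, spec, seed = 1), "clipped")
})

test_that("T-maze correctness follows the alternation rule", {
  ss <- simulate_tmaze_session(50, correct_rate = 1, spec = NULL, seed = 3)
  expect_true(all(ss$trials$correct))
  expect_true(all(ss$trials$free_choice != ss$trials$forced_side))
  expect_identical(ss$trials$correct,
                   ss$trials$free_choice != ss$trials$forced_side)
  big <- simulate_tmaze_session(10000, correct_rate = 0.5, spec = NULL,
                                seed = 11)
  expect_lt(abs(correct_choice_rate(big) - 50), 1.5)
  expect_error(simulate_tmaze_session(0), ">= 1")
  expect_error(simulate_tmaze_session(10, correct_rate = 1.4), "\\[0, 1\\]")
})

test_that("every trial contains full forced-arm and decision windows", {
  ss <- simulate_tmaze_session(30, spec = NULL, seed = 5)
  tdur <- ss$timing$trial_duration_s
  t0 <- (ss$trials$trial_id - 1) * tdur
  expect_true(all(ss$trials$forced_turn_time_s + 5 <= t0 + tdur))
  expect_true(all(ss$trials$free_choice_turn_time_s - 6 >= t0))
  expect_true(all(ss$trials$free_choice_turn_time_s <= t0 + tdur))
  expect_error(tmaze_timing(trial_duration_s = 10, forced_turn_s = 8),
               "does not fit")
  expect_error(tmaze_timing(free_choice_turn_s = 5), "does not fit")
})

test_that("LR-tuned neurons fire differentially by side in their window", {
  spec <- make_tuning_spec(40, seed = 8,
                           gain_ranges = list(lr_arm = c(0.9, 1),
                                              lr_decision = c(0, 0)))
  spec$baseline_rate <- 0.1  # dense enough to see the contrast quickly
  ss <- simulate_tmaze_session(50, spec = spec, seed = 2)
  act <- extract_period_activity(ss, "forced_arm")
  li <- lr_index(act)
  agree <- sign(li$lr_index) == spec$lr_arm_pref
  expect_gt(mean(agree[!li$inactive]), 0.8)
})
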
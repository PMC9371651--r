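dt3 <- 1 / 3

test_that("information content matches analytic values", {
  # 4 equally occupied bins, all events in one -> 2 bits
  labels <- rep(1:4, each = 60)
  ev <- integer(240)
  ev[labels == 2][1:10] <- 1L
  expect_equal(information_content(ev, labels, dt3)$info, 2, tolerance = 1e-12)
  # identical rates across bins -> 0 bits
  ev_flat <- rep(c(1L, 0L, 0L), 80)
  expect_equal(information_content(ev_flat, labels, dt3)$info, 0,
               tolerance = 1e-12)
  # p = (.5, .5), lambda = (r, 0) -> 1 bit
  labels2 <- rep(1:2, each = 120)
  ev2 <- integer(240)
  ev2[1:20] <- 1L
  expect_equal(information_content(ev2, labels2, dt3)$info, 1,
               tolerance = 1e-12)
})

test_that("information content matches a brute-force oracle on random instances", {
  for (s in 1:20) {
    inst <- random_info_instance(s)
    got <- information_content(inst$events, inst$labels, inst$dt)$info
    want <- skaggs_bruteforce(inst$events, inst$labels, inst$dt)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("information is invariant to bin relabeling and joint circular shifts", {
  inst <- random_info_instance(99)
  base <- information_content(inst$events, inst$labels, inst$dt)$info
  perm <- sample(max(inst$labels))
  expect_equal(information_content(inst$events, perm[inst$labels],
                                   inst$dt)$info,
               base, tolerance = 1e-12)
  k <- floor(length(inst$events) / 3)
  rot <- function(v) c(v[-(1:k)], v[1:k])
  expect_equal(information_content(rot(inst$events), rot(inst$labels),
                                   inst$dt)$info,
               base, tolerance = 1e-12)
})

test_that("concentrating events into fewer bins never decreases information", {
  # equal-occupancy instances; move all events of the weakest active bin
  # into the strongest bin and compare via the brute-force oracle
  for (s in 1:10) {
    set.seed(s)
    n_bins <- sample(3:6, 1)
    labels <- rep(seq_len(n_bins), each = 50)
    counts <- rpois(n_bins, 3) + c(2, rep(0, n_bins - 1))
    ev <- integer(length(labels))
    for (b in seq_len(n_bins)) {
      if (counts[b] > 0) ev[labels == b][seq_len(min(counts[b], 50))] <- 1L
    }
    active <- which(tapply(ev, labels, sum) > 0)
    if (length(active) < 2) next
    lo <- active[which.min(tapply(ev, labels, sum)[active])]
    hi <- active[which.max(tapply(ev, labels, sum)[active])]
    ev2 <- ev
    n_move <- sum(ev[labels == lo])
    ev2[labels == lo] <- 0L
    free <- which(labels == hi & ev2 == 0L)
    ev2[free[seq_len(n_move)]] <- 1L
    expect_gte(skaggs_bruteforce(ev2, labels, dt3) + 1e-12,
               skaggs_bruteforce(ev, labels, dt3))
  }
})

test_that("low-occupancy bins are excluded and renormalized", {
  labels <- c(rep(1L, 60), rep(2L, 60), 3L)  # bin 3: 1 frame (1/3 s) only
  ev <- integer(121)
  ev[1:10] <- 1L
  ev[121] <- 1L  # event in the excluded bin must be ignored
  res <- information_content(ev, labels, dt3, min_occupancy_s = 1)
  expect_identical(which(res$included), 1:2)
  expect_equal(sum(res$p), 1, tolerance = 1e-12)
  expect_equal(res$n_events, 10)
  expect_equal(res$info, 1, tolerance = 1e-12)
  expect_error(information_content(ev, rep(1L, 121), dt3), "fewer than 2")
})

test_that("shuffle null has the requested size and matches manual shifts", {
  tr <- simulate_of_trajectory(600, 3, seed = 13)
  st <- discretize_states(compute_kinematics(tr), tr)
  set.seed(1)
  ev <- as.integer(runif(1800) < 0.02)
  null <- shuffle_null(ev, st$position_bin, dt3, n_shuffles = 50,
                       min_shift_s = 20, seed = 77)
  expect_length(null, 50)
  # replicate the internal offset stream and verify against direct
  # recomputation on manually shifted trains
  lo <- ceiling(20 / dt3); hi <- floor((600 - 20) / dt3)
  set.seed(77L)
  offsets <- sample(lo:hi, 50, replace = TRUE)
  n <- length(ev)
  for (k in c(1, 25, 50)) {
    o <- offsets[k]
    shifted <- ev[((seq_len(n) - 1 - o) %% n) + 1]
    expect_equal(sum(shifted), sum(ev))  # count preserved by the shift
    expect_equal(null[k],
                 information_content(shifted, st$position_bin, dt3)$info,
                 tolerance = 1e-12)
  }
  expect_error(shuffle_null(ev, st$position_bin, dt3, 10,
                            min_shift_s = 400, seed = 1),
               "shorter than twice")
})

test_that("neurons without events have undefined information", {
  labels <- rep(1:4, each = 30)
  res <- information_content(integer(120), labels, dt3)
  expect_true(is.na(res$info))
  expect_false(res$defined)
  expect_true(all(is.na(shuffle_null(integer(120), labels, dt3, 10,
                                     min_shift_s = 5, seed = 1))))
})

test_that("population test reports exceedance fraction and null-consistent effects", {
  set.seed(5)
  null <- matrix(runif(1000 * 10), 1000, 10)
  obs <- c(rep(0.5, 8), 1.5, 1.5)  # 2 of 10 neurons above any null value
  res <- population_shuffle_test(obs, null, seed = 2)
  expect_equal(res$frac_above_p95, 20)
  expect_equal(res$n_neurons, 10)
  # observed equal to the null means -> d ~ 0, p not extreme
  obs0 <- colMeans(null)
  res0 <- population_shuffle_test(obs0, null, seed = 3)
  expect_lt(abs(res0$cohens_d), 0.2)
  expect_gt(res0$p_value, 0.05)
  expect_error(population_shuffle_test(1, matrix(1, 10, 1)), ">= 2 neurons")
})

test_that("a strongly tuned population is detected by the permutation test", {
  tr <- simulate_of_trajectory(900, 3, seed = 31)
  st <- discretize_states(compute_kinematics(tr), tr)
  spec <- make_tuning_spec(25, seed = 3,
                           gain_ranges = list(place = c(0.9, 1),
                                              speed = c(0, 0),
                                              direction = c(0, 0)),
                           place_width_range = c(3, 5))
  spec$baseline_rate <- 0.06
  rec <- generate_events(tr, spec, seed = 4)
  res <- lapply(seq_len(25), function(j) {
    info_result(rec$events[, j], st$position_bin, dt3, n_shuffles = 200,
                seed = j)
  })
  pt <- population_info_test(res, seed = 9)
  expect_lt(pt$p_value, 0.01)
  expect_gt(pt$cohens_d, 0.5)
})
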
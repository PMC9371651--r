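fake_result <- function(target, pred, obs) {
  structure(list(target = target, predictions = pred, observed = obs,
                 metric_name = dgcoding:::metric_name_for(target)),
            class = "decoding_result")
}

test_that("evaluate() returns perfect scores for perfect predictions", {
  xy <- cbind(runif(50, 0, 40), runif(50, 0, 40))
  expect_equal(evaluate(fake_result("position", xy, xy)), 0)
  v <- runif(50, 0, 10)
  expect_equal(evaluate(fake_result("speed", v, v)), 1)
  th <- runif(50, -pi, pi)
  expect_equal(evaluate(fake_result("direction", th, th)), 0)
  lr <- factor(rep(c("L", "R"), 5))
  expect_equal(evaluate(fake_result("lr", lr, lr)), 100)
})

test_that("evaluate() computes the documented metrics", {
  pred <- cbind(c(0, 3), c(0, 4))
  obs <- cbind(c(3, 0), c(4, 0))
  expect_equal(evaluate(fake_result("position", pred, obs)), 5)  # both 3-4-5
  # direction error wraps: pi/2 past pi comes back
  expect_equal(evaluate(fake_result("direction", c(pi, 0), c(-pi / 2, pi))),
               mean(c(pi / 2, pi)))
  lr <- factor(c(rep("L", 7), rep("R", 3)), levels = c("L", "R"))
  obs_lr <- factor(rep("L", 10), levels = c("L", "R"))
  expect_equal(evaluate(fake_result("lr", lr, obs_lr)), 70)
  expect_warning(
    out <- evaluate(fake_result("speed", runif(10), rep(2, 10))),
    "zero variance")
  expect_true(is.na(out))
})

test_that("uniform random direction predictions sit at pi/2 error", {
  set.seed(42)
  pred <- runif(1e4, -pi, pi)
  obs <- runif(1e4, -pi, pi)
  err <- evaluate(fake_result("direction", pred, obs))
  expect_lt(abs(err - pi / 2), 0.03)
})

test_that("a population that linearly encodes x is decoded far below chance", {
  set.seed(8)
  n <- 900
  x <- 20 + 18 * sin(seq(0, 12 * pi, length.out = n)) * runif(n, 0.6, 1)
  # y constant: the error metric then isolates the encoded coordinate
  tr <- make_traj(pmin(pmax(x, 0), 40), rep(20, n))
  bands <- seq(0, 40, length.out = 11)
  events <- sapply(1:10, function(j) {
    as.integer(x >= bands[j] & x < bands[j + 1])
  })
  res <- train_and_decode(events, tr, "position", model = "linear",
                          window = 3, folds = 5, seed = 1)
  ch <- chance_level(events, tr, "position", model = "linear",
                     n_reps = 3, min_shift_s = 30, window = 3, seed = 2)
  expect_lt(res$metric / ch$mean, 0.5)
  expect_length(res$frames, n)  # one prediction per evaluable frame
})

test_that("held-out predictions do not depend on held-out targets", {
  set.seed(3)
  tr <- simulate_of_trajectory(200, 3, seed = 3)
  events <- matrix(rbinom(600 * 8, 1, 0.1), 600, 8)
  r1 <- train_and_decode(events, tr, "position", folds = 4, seed = 5)
  tr2 <- tr
  fold1 <- 1:150  # first contiguous fold
  tr2$x_cm[fold1] <- rev(tr2$x_cm[fold1])  # corrupt held-out targets only
  r2 <- train_and_decode(events, tr2, "position", folds = 4, seed = 5)
  expect_equal(r1$predictions[fold1, ], r2$predictions[fold1, ],
               tolerance = 1e-10)
})

test_that("duplicating a neuron barely changes ridge predictions", {
  set.seed(4)
  tr <- simulate_of_trajectory(200, 3, seed = 4)
  events <- matrix(rbinom(600 * 6, 1, 0.15), 600, 6)
  r1 <- train_and_decode(events, tr, "position", lambda = 0.1, seed = 1)
  r2 <- train_and_decode(cbind(events, events[, 6]), tr, "position",
                         lambda = 0.1, seed = 1)
  expect_gt(cor(r1$predictions[, 1], r2$predictions[, 1]), 0.999)
  expect_lt(mean(abs(r1$predictions - r2$predictions)), 0.1)
})

test_that("feedforward and recurrent decoders run and return finite metrics", {
  set.seed(6)
  tr <- simulate_of_trajectory(150, 3, seed = 6)
  events <- matrix(rbinom(450 * 5, 1, 0.1), 450, 5)
  rf <- train_and_decode(events, tr, "speed", model = "feedforward",
                         window = 3, hidden = 4, seed = 2)
  expect_true(is.finite(rf$metric))
  rr <- train_and_decode(events, tr, "speed", model = "recurrent",
                         hidden = 16, seed = 2)
  expect_true(is.finite(rr$metric))
  # recurrent model is reproducible given the seed
  rr2 <- train_and_decode(events, tr, "speed", model = "recurrent",
                          hidden = 16, seed = 2)
  expect_equal(rr$metric, rr2$metric)
})

test_that("LR decoding is perfect for separable counts and chance for shuffled labels", {
  spec <- make_tuning_spec(40, seed = 31,
                           gain_ranges = list(lr_arm = c(0.9, 1)))
  ss <- simulate_tmaze_session(50, spec = spec, seed = 32)
  act <- extract_period_activity(ss, "forced_arm")
  res <- decode_lr(act, seed = 1)
  expect_gt(res$metric, 80)
  expect_length(res$predictions, nrow(act$counts))
  ch <- lr_chance_level(act, n_reps = 6, seed = 3)
  expect_gt(ch$mean, 25)
  expect_lt(ch$mean, 75)
})

test_that("decoders validate their inputs", {
  tr <- simulate_of_trajectory(100, 3, seed = 1)
  ev <- matrix(rbinom(300 * 3, 1, 0.1), 300, 3)
  expect_error(train_and_decode(ev[1:100, ], tr, "position"),
               "frame count")
  ev_bad <- ev
  storage.mode(ev_bad) <- "double"
  ev_bad[5, 1] <- NaN
  expect_error(train_and_decode(ev_bad, tr, "position"), "non-finite")
  expect_error(train_and_decode(ev, tr, "position", folds = 1), "2 CV folds")
})
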
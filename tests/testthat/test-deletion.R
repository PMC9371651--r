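
# curves with exact per-level SD 1 across 4 animals: group B = group A + 1
# so Cohen's d (pooled SD) is exactly 1 at every level
unit_sd_curves <- function() {
  base <- c(-3, -1, 1, 3) / sqrt(sum(c(-3, -1, 1, 3)^2) / 3)  # sd exactly 1
  levels <- seq(100, 10, by = -10)
  perf <- array(NA_real_, c(4, 2, 10))
  for (l in seq_along(levels)) {
    perf[, 1, l] <- base + l        # order A
    perf[, 2, l] <- base + l + 1    # order B: mean shifted by +1
  }
  as_deletion_curves(perf, c("A", "B"), levels)
}

test_that("pairwise effect size reproduces the hand-computed unit case", {
  cv <- unit_sd_curves()
  es <- pairwise_effect_size(cv, "A", "B")
  expect_length(es$d, 9)
  expect_identical(names(es$d), paste0(seq(90, 10, by = -10), "%"))
  expect_equal(unname(es$d), rep(-1, 9), tolerance = 1e-12)
  expect_equal(es$mean_abs_d, 1, tolerance = 1e-12)
  # identical curves -> d = 0 everywhere
  cv$performance[, 2, ] <- cv$performance[, 1, ]
  expect_equal(pairwise_effect_size(cv, "A", "B")$mean_abs_d, 0)
})

test_that("effect sizes are invariant under uniform performance scaling", {
  cv <- unit_sd_curves()
  d1 <- pairwise_effect_size(cv, "A", "B")$d
  cv2 <- as_deletion_curves(cv$performance * 7.3, cv$orders, cv$levels)
  expect_equal(pairwise_effect_size(cv2, "A", "B")$d, d1, tolerance = 1e-9)
})

test_that("effect-size matrix is symmetric with zero diagonal and duplicate-order zeros", {
  set.seed(10)
  perf <- array(rnorm(5 * 5 * 10), c(5, 5, 10))
  perf[, 5, ] <- perf[, 4, ]  # order 5 duplicates order 4
  cv <- as_deletion_curves(perf, paste0("o", 1:5), seq(100, 10, by = -10))
  m <- effect_size_matrix(cv)
  expect_equal(dim(m), c(5, 5))
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(diag(m) == 0))
  expect_equal(m["o4", "o5"], 0)
  expect_true(all(m[upper.tri(m)][-10] > 0))
})

test_that("order ANOVA has the (k-1, (k-1)(L-1)) design and detects separation", {
  set.seed(11)
  perf <- array(rnorm(7 * 5 * 10, sd = 0.1), c(7, 5, 10))
  perf[, 2, ] <- perf[, 2, ] + 3  # one clearly different order
  cv <- as_deletion_curves(perf, paste0("o", 1:5), seq(100, 10, by = -10))
  an <- compare_orders_anova(cv)
  expect_identical(unname(an$order_df), c(4, 36))
  expect_lt(an$order_p, 0.001)
  expect_true(!is.null(an$posthoc))
  # identical data in every order -> F ~ 0, p ~ 1
  perf0 <- perf
  for (o in 2:5) perf0[, o, ] <- perf0[, 1, ]
  an0 <- compare_orders_anova(as_deletion_curves(perf0, paste0("o", 1:5),
                                                 seq(100, 10, by = -10)))
  expect_lt(an0$order_F, 1e-10)
  expect_gt(an0$order_p, 0.999)
  # unbalanced designs are refused
  perf_na <- perf
  perf_na[1, 1, 1] <- NA
  expect_error(compare_orders_anova(
    as_deletion_curves(perf_na, paste0("o", 1:5), seq(100, 10, by = -10))),
    "unbalanced")
})

test_that("retention sets are nested and ordered deletion removes top scores first", {
  sc <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 0)
  del_seq <- order(sc, decreasing = TRUE)  # deletion order used for *_desc
  expect_equal(del_seq[1], 3L)  # maximal score deleted first
  prev <- NULL
  for (lv in seq(100, 10, by = -10)) {
    kept <- dgcoding:::retained_set(del_seq, lv)
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  expect_false(3L %in% dgcoding:::retained_set(del_seq, 90))
})

test_that("deletion curves anchor at the full-population metric and track scores", {
  set.seed(12)
  sessions <- list()
  scores <- list()
  for (a in 1:2) {
    tr <- simulate_of_trajectory(200, 3, seed = 40 + a)
    spec <- make_tuning_spec(12, seed = 50 + a,
                             gain_ranges = list(place = c(0.9, 1),
                                                speed = c(0, 0),
                                                direction = c(0, 0)),
                             place_width_range = c(3, 5))
    spec$baseline_rate <- 0.2
    rec <- generate_events(tr, spec, seed = 60 + a)
    st <- discretize_states(compute_kinematics(tr), tr)
    info <- apply(rec$events, 2, function(e) {
      out <- tryCatch(information_content(e, st$position_bin, 1 / 3)$info,
                      error = function(cond) NA_real_)
      if (is.na(out)) 0 else out
    })
    sessions[[a]] <- list(recording = rec, trajectory = tr)
    scores[[a]] <- cbind(spatial = info)
  }
  cv <- deletion_curves(sessions, "position", scores,
                        orders = c("random", "spatial_desc"),
                        levels = c(100, 50), n_random = 3,
                        window = 5, folds = 4, seed = 9)
  full <- train_and_decode(sessions[[1]]$recording,
                           sessions[[1]]$trajectory, "position",
                           window = 5, folds = 4, seed = 9)
  expect_equal(cv$performance[1, "random", "100%"], full$metric,
               tolerance = 1e-9)
  expect_equal(cv$performance[1, "spatial_desc", "100%"], full$metric,
               tolerance = 1e-9)
  expect_error(deletion_curves(sessions, "position", scores,
                               orders = "bogus_desc"),
               "unknown deletion order")
})

test_that("LR deletion curves run on period activity", {
  spec <- make_tuning_spec(16, seed = 71,
                           gain_ranges = list(lr_arm = c(0.8, 1)))
  sessions <- list()
  scores <- list()
  for (a in 1:2) {
    ss <- simulate_tmaze_session(20, spec = spec, seed = 80 + a)
    act <- extract_period_activity(ss, "forced_arm")
    sessions[[a]] <- act
    scores[[a]] <- cbind(lr_arm = abs(lr_index(act)$lr_index))
  }
  cv <- deletion_curves(sessions, "lr", scores,
                        orders = c("random", "lr_arm_desc"),
                        levels = c(100, 50), n_random = 2, seed = 3)
  expect_true(all(is.finite(cv$performance)))
  expect_true(all(cv$performance >= 0 & cv$performance <= 100))
})
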
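# Population decoding of position, speed, motion direction (open field)
# and left/right location (T-maze), with shuffled-data chance levels.
#
# Decoders:
#   linear      ridge (Wiener-filter style) regression on a sliding
#               window of population event vectors; closed form, the
#               default for tests and for the deletion analysis.
#   feedforward one-hidden-layer network (nnet) on the same features.
#   recurrent   echo-state network: a fixed random leaky-tanh recurrent
#               reservoir driven by the event sequence, with a ridge
#               readout. Seed-controlled; the package's recurrent
#               sequence decoder.
#
# Continuous targets (x/y position, speed) are regressed per frame;
# direction is regressed as (sin, cos) and recomposed with atan2, which
# avoids the 2*pi discontinuity. Cross-validation uses contiguous
# temporal folds so that autocorrelated frames do not leak between train
# and test. LR location is decoded per trial from period count vectors
# with leave-one-trial-out CV.

#' Sliding-window feature matrix
#'
#' Row t holds the population event vectors of frames t-window+1 .. t
#' (zero-padded at the session start), lag 0 first. Columns are grouped
#' by lag, neurons fastest, so neuron j occupies columns
#' `j + lag * n_neurons`.
#'
#' @param events binary frames x neurons matrix.
#' @param window number of frames per window (default 10, ~3.3 s at 3 Hz).
#' @return numeric matrix, frames x (neurons * window).
#' @export
build_features <- function(events, window = 10L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  n <- nrow(events)
  p <- ncol(events)
  X <- matrix(0, n, p * window)
  for (l in 0:(window - 1L)) {
    X[(1L + l):n, (l * p + 1L):((l + 1L) * p)] <-
      events[1L:(n - l), , drop = FALSE]
  }
  X
}

neuron_columns <- function(neurons, n_neurons, window) {
  as.vector(outer(as.integer(neurons), (0:(window - 1L)) * n_neurons, `+`))
}

ridge_coef <- function(Gc, Ac, lambda) {
  p <- nrow(Gc)
  solve(Gc + diag(lambda, p), Ac)
}

# Per-fold sufficient statistics for ridge: centered Gram and
# cross-product, reusable across neuron subsets (columns of X).
fold_stats <- function(X, Y, train) {
  Xtr <- X[train, , drop = FALSE]
  Ytr <- Y[train, , drop = FALSE]
  n <- nrow(Xtr)
  mu <- colMeans(Xtr)
  nu <- colMeans(Ytr)
  list(Gc = crossprod(Xtr) - n * tcrossprod(mu),
       Ac = crossprod(Xtr, Ytr) - n * outer(mu, nu),
       mu = mu, nu = nu, n = n)
}

ridge_predict <- function(stats, B, Xte, cols = NULL) {
  mu <- if (is.null(cols)) stats$mu else stats$mu[cols]
  sweep(Xte, 2, mu) %*% B + rep(stats$nu, each = nrow(Xte))
}

contiguous_folds <- function(n, folds) {
  if (folds < 2L) stop("need at least 2 CV folds")
  sort(rep_len(seq_len(folds), n))
}

decoding_targets <- function(trajectory, target) {
  kin <- compute_kinematics(trajectory)
  n <- nrow(kin)
  switch(target,
    position = list(Y = cbind(trajectory$x_cm, trajectory$y_cm),
                    obs = cbind(trajectory$x_cm, trajectory$y_cm),
                    valid = rep(TRUE, n)),
    speed = list(Y = matrix(kin$speed, ncol = 1),
                 obs = kin$speed,
                 valid = is.finite(kin$speed)),
    direction = list(Y = cbind(sin(kin$direction), cos(kin$direction)),
                     obs = kin$direction,
                     valid = kin$valid_direction),
    stop("unknown target: ", target))
}

#' Decode a behavioural variable from population activity
#'
#' Trains the requested decoder with contiguous-fold cross-validation
#' and returns out-of-fold predictions for every evaluable frame.
#'
#' @param recording a `population_recording` (or plain binary matrix).
#' @param trajectory the aligned `trajectory`.
#' @param target `"position"`, `"speed"` or `"direction"`.
#' @param model `"linear"` (default), `"feedforward"` or `"recurrent"`.
#' @param window sliding-window length in frames.
#' @param folds number of contiguous temporal folds (default 5).
#' @param lambda ridge penalty (linear and recurrent readout).
#' @param hidden hidden units (feedforward) or reservoir size (recurrent).
#' @param seed integer seed (controls network initialization; the linear
#'   model is deterministic).
#' @return a `decoding_result`: `target`, `model`, `metric_name`,
#'   `metric` (via [evaluate()]), `predictions`, `observed`, `frames`
#'   (evaluated frame indices), `fold`.
#' @export
train_and_decode <- function(recording, trajectory,
                             target = c("position", "speed", "direction"),
                             model = c("linear", "feedforward", "recurrent"),
                             window = 10L, folds = 5L, lambda = 1,
                             hidden = 64L, seed = 1L) {
  target <- match.arg(target)
  model <- match.arg(model)
  events <- if (inherits(recording, "population_recording"))
    recording$events else recording
  if (is.null(dim(events)) || ncol(events) < 1L) {
    stop("recording must contain at least one neuron")
  }
  n <- nrow(events)
  if (n != n_frames(trajectory)) {
    stop("recording and trajectory differ in frame count")
  }
  tg <- decoding_targets(trajectory, target)

  X <- if (model == "recurrent") {
    esn_states(events, size = hidden, seed = seed)
  } else {
    build_features(events, window)
  }
  if (any(!is.finite(X))) stop("non-finite decoder features")

  fold_id <- contiguous_folds(n, folds)
  q <- ncol(tg$Y)
  pred_raw <- matrix(NA_real_, n, q)
  set.seed(as.integer(seed))
  for (f in seq_len(folds)) {
    train <- fold_id != f & tg$valid
    test <- fold_id == f & tg$valid
    if (!any(test)) next
    if (sum(train) < 2L) stop("a CV fold has no training data")
    if (model == "feedforward") {
      fit <- nnet::nnet(x = X[train, , drop = FALSE],
                        y = tg$Y[train, , drop = FALSE],
                        size = min(hidden, 32L), linout = TRUE,
                        decay = 0.1, maxit = 100, trace = FALSE,
                        MaxNWts = 100000L)
      pred_raw[test, ] <- as.matrix(stats::predict(fit, X[test, , drop = FALSE]))
    } else {
      st <- fold_stats(X, tg$Y, train)
      B <- ridge_coef(st$Gc, st$Ac, lambda)
      pred_raw[test, ] <- ridge_predict(st, B, X[test, , drop = FALSE])
    }
  }

  frames <- which(tg$valid)
  predictions <- switch(target,
    position = pred_raw[frames, , drop = FALSE],
    speed = pred_raw[frames, 1],
    direction = atan2(pred_raw[frames, 1], pred_raw[frames, 2]))
  observed <- if (target == "position") tg$obs[frames, , drop = FALSE]
              else tg$obs[frames]

  out <- structure(list(target = target, model = model,
                        predictions = predictions, observed = observed,
                        frames = frames, fold = fold_id[frames],
                        metric_name = metric_name_for(target),
                        window = window, lambda = lambda, seed = seed),
                   class = "decoding_result")
  out$metric <- evaluate(out)
  out
}

metric_name_for <- function(target) {
  switch(target,
         position = "mean_absolute_error_cm",
         speed = "pearson_r",
         direction = "mean_absolute_circular_error_rad",
         lr = "accuracy_percent")
}

#' Evaluate a decoding result
#'
#' Position: mean absolute Euclidean error (cm). Speed: Pearson
#' correlation between observed and decoded speed. Direction: mean
#' absolute circular error (radians, in \[0, pi\]). LR: percentage of
#' correctly classified trials.
#'
#' @param result a `decoding_result`.
#' @return scalar metric value.
#' @export
evaluate <- function(result) {
  stopifnot(inherits(result, "decoding_result"))
  pred <- result$predictions
  obs <- result$observed
  if (length(pred) == 0L) stop("empty predictions")
  switch(result$target,
    position = mean(sqrt(rowSums((pred - obs)^2))),
    speed = {
      if (stats::sd(obs) == 0) {
        warning("observed speed has zero variance; correlation undefined")
        NA_real_
      } else stats::cor(pred, obs)
    },
    direction = mean(circular_abs_diff(pred, obs)),
    lr = 100 * mean(pred == obs),
    stop("unknown target in result"))
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s via %s: %s = %.4g (n = %d)\n",
              x$target, x$model, x$metric_name, x$metric,
              length(x$frames)))
  invisible(x)
}

# Echo-state reservoir: h_t = (1-a) h_{t-1} + a tanh(Win e_t + W h_{t-1}).
# Win and W are fixed random draws; W is scaled to spectral radius 0.9
# (power iteration). Returns the state sequence plus the raw events as
# direct inputs to the readout.
esn_states <- function(events, size = 64L, leak = 0.5, rho = 0.9,
                       seed = 1L) {
  size <- as.integer(size)
  p <- ncol(events)
  set.seed(as.integer(derive_seed(seed, 977L)))
  Win <- matrix(stats::rnorm(size * p, sd = 1), size, p)
  W <- matrix(stats::rnorm(size * size, sd = 1 / sqrt(size)), size, size)
  v <- stats::rnorm(size)
  for (i in 1:30) v <- W %*% v / sqrt(sum((W %*% v)^2))
  sr <- sqrt(sum((W %*% v)^2) / sum(v^2))
  W <- W * (rho / sr)
  n <- nrow(events)
  H <- matrix(0, n, size)
  h <- numeric(size)
  for (t in seq_len(n)) {
    h <- (1 - leak) * h + leak * tanh(Win %*% events[t, ] + W %*% h)
    H[t, ] <- h
  }
  cbind(H, events)
}

#' Shuffled-data chance level for open-field decoding
#'
#' Each repetition circularly shifts every neuron's event train by an
#' independent random offset (at least `min_shift_s`), retrains the full
#' decoding pipeline on the shifted data, and evaluates the resulting
#' predictions against the true held-out targets. The mean over
#' repetitions is the operational chance level.
#'
#' @inheritParams train_and_decode
#' @param n_reps repetitions (default 10).
#' @param min_shift_s minimum circular shift in seconds.
#' @return a `chance_level`: list with `values` (per repetition), `mean`,
#'   `sd`, `metric_name`.
#' @export
chance_level <- function(recording, trajectory,
                         target = c("position", "speed", "direction"),
                         model = c("linear", "feedforward", "recurrent"),
                         n_reps = 10, min_shift_s = 20, window = 10L,
                         folds = 5L, lambda = 1, hidden = 64L, seed = 1L) {
  target <- match.arg(target)
  model <- match.arg(model)
  if (n_reps < 1) stop("n_reps must be >= 1")
  events <- if (inherits(recording, "population_recording"))
    recording$events else recording
  n <- nrow(events)
  rate <- if (inherits(recording, "population_recording"))
    recording$frame_rate else trajectory$frame_rate
  lo <- ceiling(min_shift_s * rate)
  hi <- n - lo
  if (lo >= hi) stop("session shorter than twice the minimum shift")

  vals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(as.integer(derive_seed(seed, r)))
    offs <- sample(lo:hi, ncol(events), replace = TRUE)
    shifted <- events
    for (j in seq_len(ncol(events))) {
      o <- offs[j]
      shifted[, j] <- events[c((n - o + 1L):n, 1L:(n - o)), j]
    }
    res <- train_and_decode(shifted, trajectory, target = target,
                            model = model, window = window, folds = folds,
                            lambda = lambda, hidden = hidden, seed = seed)
    vals[r] <- res$metric
  }
  structure(list(values = vals, mean = mean(vals), sd = stats::sd(vals),
                 metric_name = metric_name_for(target)),
            class = "chance_level")
}

#' Decode left/right location from period activity
#'
#' Binary decoding of the trial side label from the per-trial population
#' count vectors of a task window, with leave-one-trial-out
#' cross-validation. The default decoder is a ridge classifier (ridge
#' regression on +/-1 labels, classify by sign); `"feedforward"` uses a
#' single-hidden-layer network.
#'
#' @param activity a [extract_period_activity()] object.
#' @param model `"linear"` or `"feedforward"`.
#' @param lambda ridge penalty.
#' @param hidden hidden units (feedforward).
#' @param seed integer seed.
#' @param train_side optional factor of side labels to *train* on
#'   (defaults to the true labels; used for label-permuted chance runs).
#' @return a `decoding_result` with target `"lr"`; `metric` is percent
#'   correct over held-out trials.
#' @export
decode_lr <- function(activity, model = c("linear", "feedforward"),
                      lambda = 1, hidden = 8L, seed = 1L,
                      train_side = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(activity, "period_activity"))
  Xall <- activity$counts
  side <- activity$side
  train_side <- train_side %||% side
  n_t <- nrow(Xall)
  if (n_t < 3L) stop("need at least 3 trials for leave-one-trial-out CV")
  y <- ifelse(train_side == "L", 1, -1)
  pred <- character(n_t)
  set.seed(as.integer(seed))
  for (i in seq_len(n_t)) {
    tr <- setdiff(seq_len(n_t), i)
    if (model == "linear") {
      st <- fold_stats(Xall, matrix(y, ncol = 1), tr)
      B <- ridge_coef(st$Gc, st$Ac, lambda)
      sc <- ridge_predict(st, B, Xall[i, , drop = FALSE])
    } else {
      fit <- nnet::nnet(x = Xall[tr, , drop = FALSE],
                        y = matrix(y[tr], ncol = 1), size = hidden,
                        linout = TRUE, decay = 0.5, maxit = 50,
                        trace = FALSE, MaxNWts = 10000L)
      sc <- stats::predict(fit, Xall[i, , drop = FALSE])
    }
    pred[i] <- if (sc >= 0) "L" else "R"
  }
  out <- structure(list(target = "lr", model = model,
                        predictions = factor(pred, levels = c("L", "R")),
                        observed = side,
                        frames = seq_len(n_t), fold = seq_len(n_t),
                        metric_name = metric_name_for("lr"),
                        window = activity$window_s, lambda = lambda,
                        seed = seed),
                   class = "decoding_result")
  out$metric <- evaluate(out)
  out
}

#' Label-permutation chance level for LR decoding
#'
#' Each repetition permutes the trial side labels (preserving L/R
#' counts), trains the leave-one-trial-out LR decoder on the permuted
#' labels, and scores its predictions against the true labels.
#'
#' @inheritParams decode_lr
#' @param n_reps repetitions (default 10).
#' @return a `chance_level`.
#' @export
lr_chance_level <- function(activity, model = c("linear", "feedforward"),
                            n_reps = 10, lambda = 1, hidden = 8L,
                            seed = 1L) {
  model <- match.arg(model)
  vals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(as.integer(derive_seed(seed, 5000L + r)))
    perm <- sample(activity$side)
    res <- decode_lr(activity, model = model, lambda = lambda,
                     hidden = hidden, seed = seed, train_side = perm)
    vals[r] <- res$metric
  }
  structure(list(values = vals, mean = mean(vals), sd = stats::sd(vals),
                 metric_name = metric_name_for("lr")),
            class = "chance_level")
}
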
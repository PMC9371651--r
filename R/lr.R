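# Left/right selectivity in the T-maze: period activity extraction,
# LR indices and trial-label shuffle nulls.

#' Extract per-trial, per-neuron activity in a task window
#'
#' Two windows are defined relative to the turns of each trial:
#' \describe{
#'   \item{forced_arm}{0 to +5 s after the forced turn; the side label is
#'     the current arm (the forced side).}
#'   \item{decision}{-6 to -1 s before the free-choice turn; the side
#'     label is the future location, i.e. the side the animal chooses
#'     after the turn.}
#' }
#' Both windows last 5 s (15 frames at 3 Hz). Trials whose window falls
#' outside the recorded session are excluded with a warning rather than
#' truncated, keeping per-trial exposure time constant.
#'
#' @param session a [simulate_tmaze_session()] object (with a recording)
#'   or an equivalent list.
#' @param period `"forced_arm"` or `"decision"`.
#' @return a `period_activity`: list with `counts` (trials x neurons
#'   event counts), `side` (factor L/R per trial), `trial_id`,
#'   `window_s` (5), `period`, `n_excluded`.
#' @export
extract_period_activity <- function(session,
                                    period = c("forced_arm", "decision")) {
  period <- match.arg(period)
  stopifnot(inherits(session, "tmaze_session"))
  if (is.null(session$recording)) {
    stop("session carries no recording; cannot extract activity")
  }
  ev <- session$recording$events
  rate <- session$frame_rate
  n <- nrow(ev)
  times <- (seq_len(n) - 1) / rate
  trials <- session$trials

  if (period == "forced_arm") {
    start <- trials$forced_turn_time_s
    side <- trials$forced_side
  } else {
    start <- trials$free_choice_turn_time_s - 6
    side <- trials$free_choice
  }
  stop_t <- start + 5

  counts <- matrix(NA_real_, nrow(trials), ncol(ev))
  keep <- rep(TRUE, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    if (start[i] < 0 || stop_t[i] > n / rate) {
      keep[i] <- FALSE
      next
    }
    sel <- times >= start[i] & times < stop_t[i]
    counts[i, ] <- colSums(ev[sel, , drop = FALSE])
  }
  if (any(!keep)) {
    warning(sprintf("%d trial(s) excluded: %s window extends outside the session",
                    sum(!keep), period))
  }
  structure(list(counts = counts[keep, , drop = FALSE],
                 side = factor(side[keep], levels = c("L", "R")),
                 trial_id = trials$trial_id[keep],
                 neuron_ids = session$recording$neuron_ids,
                 window_s = 5,
                 period = period,
                 n_excluded = sum(!keep)),
            class = "period_activity")
}

#' Per-neuron LR index
#'
#' The LR index of a neuron is the normalized rate difference between
#' left- and right-labelled trials in the extraction window,
#' \deqn{LR = (r_L - r_R) / (r_L + r_R),}
#' with r_side the neuron's total event count on that side's trials
#' divided by the total window time on that side. It lies in \[-1, 1\];
#' positive values mean left-preferring. Neurons silent on both sides get
#' index 0 with an `inactive` flag.
#'
#' @param activity a [extract_period_activity()] object.
#' @return a data.frame of class `lr_result` with columns `neuron_id`,
#'   `lr_index`, `r_l`, `r_r`, `inactive`; attribute `period`.
#' @export
lr_index <- function(activity) {
  stopifnot(inherits(activity, "period_activity"))
  is_l <- activity$side == "L"
  n_l <- sum(is_l)
  n_r <- sum(!is_l)
  if (n_l == 0L || n_r == 0L) {
    stop("LR index undefined: all trials fall on one side")
  }
  w <- activity$window_s
  r_l <- colSums(activity$counts[is_l, , drop = FALSE]) / (n_l * w)
  r_r <- colSums(activity$counts[!is_l, , drop = FALSE]) / (n_r * w)
  denom <- r_l + r_r
  idx <- ifelse(denom > 0, (r_l - r_r) / denom, 0)
  out <- data.frame(neuron_id = activity$neuron_ids,
                    lr_index = idx, r_l = r_l, r_r = r_r,
                    inactive = denom == 0,
                    stringsAsFactors = FALSE)
  attr(out, "period") <- activity$period
  class(out) <- c("lr_result", "data.frame")
  out
}

#' Trial-label shuffle null for LR indices
#'
#' Each shuffle permutes the trial side labels (preserving the number of
#' L and R trials, which keeps the per-side exposure times fixed) and
#' recomputes every neuron's LR index. Trials are exchangeable under the
#' null of no side selectivity, making label permutation the natural null
#' for trial-structured data. The significance threshold is the 95th
#' percentile of the absolute null index per neuron.
#'
#' @param activity a [extract_period_activity()] object.
#' @param n_shuffles number of label permutations (default 1000).
#' @param seed integer seed.
#' @return a `lr_null`: list with `null` (n_shuffles x neurons matrix of
#'   indices), `p95_abs` (per-neuron 95th percentile of |null|),
#'   `exceeds_p95_abs` (|observed| > threshold).
#' @export
lr_shuffle_null <- function(activity, n_shuffles = 1000, seed = 1L) {
  stopifnot(inherits(activity, "period_activity"))
  is_l <- activity$side == "L"
  n_l <- sum(is_l)
  n_t <- length(is_l)
  if (n_l == 0L || n_l == n_t) {
    stop("LR null undefined: all trials fall on one side")
  }
  w <- activity$window_s
  tot <- colSums(activity$counts)
  set.seed(as.integer(seed))
  null <- matrix(NA_real_, n_shuffles, ncol(activity$counts))
  for (s in seq_len(n_shuffles)) {
    perm_l <- sample.int(n_t, n_l)
    c_l <- colSums(activity$counts[perm_l, , drop = FALSE])
    r_l <- c_l / (n_l * w)
    r_r <- (tot - c_l) / ((n_t - n_l) * w)
    denom <- r_l + r_r
    null[s, ] <- ifelse(denom > 0, (r_l - r_r) / denom, 0)
  }
  obs <- lr_index(activity)
  p95 <- apply(abs(null), 2, stats::quantile, 0.95, names = FALSE)
  structure(list(null = null, p95_abs = p95,
                 exceeds_p95_abs = abs(obs$lr_index) > p95,
                 period = activity$period),
            class = "lr_null")
}

#' Population permutation test for LR selectivity
#'
#' Applies [population_shuffle_test()] to absolute LR indices against
#' their trial-label shuffle null, mirroring the population test used
#' for information content.
#'
#' @param lr a [lr_index()] result.
#' @param null a [lr_shuffle_null()] result for the same activity.
#' @param ... passed to [population_shuffle_test()].
#' @return a `population_test`.
#' @export
population_lr_test <- function(lr, null, ...) {
  population_shuffle_test(lr$lr_index, null$null, absolute = TRUE, ...)
}
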
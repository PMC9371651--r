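# Skaggs information content with circular-shift shuffle nulls and the
# population-level permutation test.
#
# The statistic is the classic per-event information of Skaggs and
# colleagues, reported here in bits per calcium transient:
#
#   I = sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda)
#
# with p_i the occupancy probability of state bin i, lambda_i the event
# rate in bin i and lambda the occupancy-weighted mean rate. For a
# binarized event train the expression reduces to a function of per-bin
# event counts and occupancy alone:
#   I = sum_i (c_i / C) log2( c_i T / (o_i C) ),
# which is what the implementation evaluates (it is exactly algebraically
# equivalent and lets the shuffle null be vectorized over shifts).

#' Skaggs information content of one neuron (bits per transient)
#'
#' Bins whose occupancy falls below `min_occupancy_s` are excluded and
#' the occupancy distribution renormalized over the remaining bins;
#' rarely visited bins otherwise contribute unstable rate estimates.
#' Neurons with zero events inside the included bins have undefined
#' information (`info = NA`, `defined = FALSE`).
#'
#' @param events binary event vector (one value per frame).
#' @param labels integer state label per frame (position bin, speed class
#'   or direction bin); `NA` frames are excluded.
#' @param dt frame duration in seconds.
#' @param min_occupancy_s occupancy threshold per bin (s, default 1).
#' @return an `info_content` list: `info` (bits/transient), `p`
#'   (occupancy probabilities over included bins), `lambda` (per-bin
#'   rates), `lambda_mean`, `n_events`, `included`, `defined`.
#' @export
information_content <- function(events, labels, dt, min_occupancy_s = 1) {
  events <- as_event_vector(events)
  if (length(events) != length(labels)) {
    stop("events and labels differ in length")
  }
  if (dt <= 0) stop("dt must be positive")
  labels <- as.integer(labels)
  nb <- max(labels, na.rm = TRUE)
  occ <- tabulate(labels, nb) * dt
  include <- occ >= min_occupancy_s & occ > 0
  if (sum(include) < 2L) {
    stop("fewer than 2 state bins pass the occupancy threshold")
  }
  cnt <- tabulate(labels[events == 1L], nb)
  info <- info_from_counts(cnt[include], occ[include])
  total_t <- sum(occ[include])
  structure(list(info = info,
                 p = occ[include] / total_t,
                 lambda = cnt[include] / occ[include],
                 lambda_mean = sum(cnt[include]) / total_t,
                 n_events = sum(cnt[include]),
                 included = include,
                 defined = !is.na(info)),
            class = "info_content")
}

# counts c_i and occupancy o_i over included bins -> bits per event
info_from_counts <- function(cnt, occ) {
  C <- sum(cnt)
  if (C == 0) return(NA_real_)
  T <- sum(occ)
  pos <- cnt > 0
  sum((cnt[pos] / C) * log2(cnt[pos] * T / (occ[pos] * C)))
}

#' Circular-shift shuffle null for information content
#'
#' Each shuffle circularly shifts the event train relative to behaviour
#' by a uniform offset in `[min_shift_s, T - min_shift_s]` and recomputes
#' the information content against the fixed state labels. The shift
#' preserves the event count and the train's internal temporal structure
#' while destroying its relation to behaviour, the standard null for
#' tuning significance.
#'
#' @inheritParams information_content
#' @param n_shuffles number of shuffles (default 1000).
#' @param min_shift_s minimum shift in seconds (default 20).
#' @param seed integer seed.
#' @return numeric vector of `n_shuffles` null information values (NA
#'   where a shifted train has no event in an included bin).
#' @export
shuffle_null <- function(events, labels, dt, n_shuffles = 1000,
                         min_shift_s = 20, min_occupancy_s = 1, seed = 1L) {
  events <- as_event_vector(events)
  n <- length(events)
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  total_s <- n * dt
  lo <- ceiling(min_shift_s / dt)
  hi <- floor((total_s - min_shift_s) / dt)
  if (min_shift_s * 2 >= total_s || lo > hi) {
    stop("session shorter than twice the minimum shift")
  }
  labels <- as.integer(labels)
  nb <- max(labels, na.rm = TRUE)
  occ <- tabulate(labels, nb) * dt
  include <- occ >= min_occupancy_s & occ > 0  # must match information_content()
  occ_in <- occ[include]
  bin_of <- match(seq_len(nb), which(include))  # NA for excluded bins

  ev <- which(events == 1L)
  if (length(ev) == 0L) {
    return(rep(NA_real_, n_shuffles))
  }
  set.seed(as.integer(seed))
  offsets <- sample(lo:hi, n_shuffles, replace = TRUE)
  shifted <- outer(ev - 1L, offsets, `+`) %% n + 1L  # events x shuffles
  lab <- matrix(labels[shifted], nrow = length(ev))
  comp <- matrix(bin_of[lab], nrow = length(ev))     # compact bin index

  nbi <- length(occ_in)
  keep <- !is.na(comp)
  shuf_col <- col(comp)[keep]
  key <- (shuf_col - 1L) * nbi + comp[keep]
  cnt <- matrix(tabulate(key, nbi * n_shuffles), nbi, n_shuffles)

  Cs <- colSums(cnt)
  Tt <- sum(occ_in)
  ratio <- sweep(cnt / occ_in, 2, Cs / Tt, `/`)      # lambda_i / lambda
  term <- (cnt / rep(Cs, each = nbi)) * log2(ratio)
  term[cnt == 0] <- 0
  out <- colSums(term)
  out[Cs == 0] <- NA_real_
  out
}

#' Information content with its shuffle null and significance flags
#'
#' Convenience wrapper combining [information_content()] and
#' [shuffle_null()] for one neuron, as used for the per-neuron
#' information histograms and their 95th-percentile thresholds.
#'
#' @inheritParams shuffle_null
#' @param min_occupancy_s occupancy threshold per bin (s).
#' @return an `info_result`: `info`, `null` (length `n_shuffles`),
#'   `null_p95`, `exceeds_p95`, `percentile` (rank of the observed value
#'   in its null, in percent), `defined`, plus the `info_content` fields.
#' @export
info_result <- function(events, labels, dt, n_shuffles = 1000,
                        min_shift_s = 20, min_occupancy_s = 1, seed = 1L) {
  base <- information_content(events, labels, dt, min_occupancy_s)
  null <- shuffle_null(events, labels, dt, n_shuffles, min_shift_s,
                       min_occupancy_s, seed)
  nl <- null[is.finite(null)]
  p95 <- if (length(nl)) stats::quantile(nl, 0.95, names = FALSE) else NA_real_
  structure(list(info = base$info,
                 null = null,
                 null_p95 = p95,
                 exceeds_p95 = isTRUE(base$info > p95),
                 percentile = if (length(nl) && base$defined)
                   100 * mean(nl < base$info) else NA_real_,
                 defined = base$defined,
                 p = base$p, lambda = base$lambda,
                 lambda_mean = base$lambda_mean,
                 n_events = base$n_events),
            class = "info_result")
}

#' Population-level permutation test on shuffle-null statistics
#'
#' Tests whether the mean observed statistic across neurons exceeds what
#' the per-neuron shuffle nulls predict. Each of `n_replicates` null
#' replicates draws one value from every neuron's null distribution and
#' averages them; the p-value is the (add-one smoothed) fraction of
#' replicate means at or above the observed mean, floored at
#' 1/(n_replicates + 1). The effect size is Cohen's d between the
#' observed values and the per-neuron null means (pooled SD), and
#' `frac_above_p95` is the percentage of neurons whose observed value
#' exceeds their own null's 95th percentile.
#'
#' @param obs numeric vector of observed per-neuron statistics.
#' @param null matrix of null values, `n_shuffles` rows x neurons
#'   columns (aligned with `obs`).
#' @param n_replicates permutation replicates (default 1000).
#' @param absolute compare absolute values (used for LR indices, whose
#'   sign is arbitrary under the null).
#' @param seed integer seed.
#' @return a `population_test`: `p_value`, `cohens_d`, `frac_above_p95`
#'   (percent), `mean_obs`, `mean_null`, `n_neurons`.
#' @export
population_shuffle_test <- function(obs, null, n_replicates = 1000,
                                    absolute = FALSE, seed = 1L) {
  if (is.list(null)) null <- do.call(cbind, null)
  keep <- is.finite(obs)
  obs <- obs[keep]
  null <- null[, keep, drop = FALSE]
  n <- length(obs)
  if (n < 2L) stop("population test needs >= 2 neurons with defined values")
  if (absolute) {
    obs <- abs(obs)
    null <- abs(null)
  }
  S <- nrow(null)
  set.seed(as.integer(seed))
  draw <- matrix(sample.int(S, n_replicates * n, replace = TRUE),
                 n_replicates, n)
  vals <- matrix(null[cbind(as.vector(draw),
                            rep(seq_len(n), each = n_replicates))],
                 n_replicates, n)
  rep_means <- rowMeans(vals, na.rm = TRUE)
  m_obs <- mean(obs)
  p <- (1 + sum(rep_means >= m_obs)) / (n_replicates + 1)

  null_means <- colMeans(null, na.rm = TRUE)
  d <- cohens_d(obs, null_means)
  p95 <- apply(null, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) stats::quantile(v, 0.95, names = FALSE) else NA_real_
  })
  structure(list(p_value = p, cohens_d = d,
                 frac_above_p95 = 100 * mean(obs > p95, na.rm = TRUE),
                 mean_obs = m_obs, mean_null = mean(null_means),
                 n_neurons = n),
            class = "population_test")
}

#' Population permutation test from a list of per-neuron info results
#'
#' @param results list of [info_result()] objects.
#' @param ... passed to [population_shuffle_test()].
#' @return a `population_test` (see [population_shuffle_test()]).
#' @export
population_info_test <- function(results, ...) {
  obs <- vapply(results, function(r) r$info %||% NA_real_, numeric(1))
  null <- vapply(results, function(r) r$null,
                 numeric(length(results[[1]]$null)))
  population_shuffle_test(obs, null, ...)
}

#' @export
print.population_test <- function(x, ...) {
  cat(sprintf(
    "<population_test> n = %d, p %s %.4g, Cohen's d = %.3f, %.1f%% above null p95\n",
    x$n_neurons, if (x$p_value <= 1 / 1000) "<" else "=",
    x$p_value, x$cohens_d, x$frac_above_p95))
  invisible(x)
}

#' Per-neuron information scores for ranking
#'
#' Computes spatial (10x10 grid), speed (3 classes) and direction (8
#' bins) information content for every neuron of a recording, as used to
#' rank neurons for ordered-deletion analyses. Neurons with undefined
#' information (no events in included bins) score 0: a silent neuron
#' carries no information.
#'
#' By default the scores are shuffle-debiased: the mean of a
#' circular-shift null is subtracted from the plug-in estimate (floored
#' at 0). The plug-in Skaggs statistic has a positive small-sample bias
#' that grows with the bin count and shrinks with the event count, so
#' with heterogeneous event rates the raw values rank sparse neurons
#' first rather than tuned ones; subtracting each neuron's own null mean
#' removes that bias. Reported information values elsewhere in the
#' package remain plug-in estimates.
#'
#' @param recording a `population_recording`.
#' @param trajectory the aligned `trajectory`.
#' @param grid spatial grid passed to [discretize_states()].
#' @param min_occupancy_s occupancy threshold per bin (s).
#' @param debias subtract the mean shuffle-null information (default
#'   TRUE).
#' @param n_shuffles shuffles per neuron for the debiasing null.
#' @param seed integer seed for the debiasing shuffles.
#' @return numeric matrix, neurons x c("spatial", "speed", "direction"),
#'   in bits per transient.
#' @export
information_scores <- function(recording, trajectory, grid = c(10L, 10L),
                               min_occupancy_s = 1, debias = TRUE,
                               n_shuffles = 100, seed = 1L) {
  kin <- compute_kinematics(trajectory)
  st <- discretize_states(kin, trajectory, grid)
  dt <- 1 / recording$frame_rate
  one <- function(labels, k) {
    vapply(seq_len(ncol(recording$events)), function(j) {
      e <- recording$events[, j]
      out <- tryCatch(
        information_content(e, labels, dt, min_occupancy_s)$info,
        error = function(cond) NA_real_)
      if (is.na(out)) return(0)
      if (debias) {
        null <- shuffle_null(e, labels, dt, n_shuffles,
                             min_occupancy_s = min_occupancy_s,
                             seed = derive_seed(seed, 3L * j + k))
        out <- max(0, out - mean(null, na.rm = TRUE))
      }
      out
    }, numeric(1))
  }
  cbind(spatial = one(st$position_bin, 0L),
        speed = one(st$speed_class, 1L),
        direction = one(st$direction_bin, 2L))
}
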
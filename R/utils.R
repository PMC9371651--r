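# Shared numeric helpers: angle arithmetic, seeds, effect sizes.

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  y <- x %% (2 * pi)
  big <- !is.na(y) & y > pi
  y[big] <- y[big] - 2 * pi
  y
}

#' Absolute circular difference
#'
#' Smallest absolute angular difference between two angles, in \[0, pi\].
#' This is the error measure used for direction decoding.
#'
#' @param a,b numeric vectors of angles (radians).
#' @return numeric vector of absolute wrapped differences.
#' @export
circular_abs_diff <- function(a, b) {
  abs(wrap_angle(a - b))
}

#' Cohen's d with pooled standard deviation
#'
#' Unpaired standardized mean difference, (mean(x) - mean(y)) / s_pooled,
#' with s_pooled the square root of the df-weighted average of the two
#' group variances.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return scalar effect size; `NaN` when both groups have zero variance.
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) {
    stop("cohens_d() needs at least 2 finite values per group")
  }
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2)
}

# Deterministic per-unit sub-seed derived from a session seed. Kept below
# 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
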
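# Population tuning specifications for the synthetic generator.

#' Draw a population tuning specification
#'
#' Describes, for each simulated neuron, how its calcium-event rate is
#' modulated by position (Gaussian place field), running speed (linear
#' ramp), motion direction (von Mises profile) and, in the T-maze,
#' left/right location in the forced-arm and decision windows.
#'
#' The `structure` argument controls the joint distribution of tuning
#' gains across neurons and encodes the three competing hypotheses about
#' how multiple information types could be distributed over a population:
#' \describe{
#'   \item{independent}{per-type gains drawn independently across neurons;
#'     population correlation between gain types is ~0 (mixed selectivity
#'     with independent allocation).}
#'   \item{dependent}{gains share a common latent factor; strongly
#'     positively correlated across types (a single "good neuron" axis).}
#'   \item{exclusive}{each neuron is strongly tuned to at most one type
#'     (or untuned), drawn from `exclusive_weights`; all other gains 0.}
#' }
#'
#' All modulation factors are normalized to have mean ~1 over the session,
#' so the population mean event rate stays at `baseline_rate` (~0.02 Hz,
#' the sparse granule-cell regime) regardless of the gains drawn.
#'
#' @param n_neurons number of neurons (default 70, the typical per-animal
#'   yield of these recordings).
#' @param structure one of `"independent"`, `"dependent"`, `"exclusive"`.
#' @param gain_ranges named list of `c(lo, hi)` ranges for `place`
#'   (0..1 mixing weight of the place bump), `speed` (fractional rate
#'   change per cm/s around mean speed), `direction` (von Mises
#'   concentration kappa), `lr_arm` and `lr_decision` (0..1 left/right
#'   modulation depth).
#' @param rate_dispersion log-scale SD of per-neuron baseline rates
#'   (lognormal across neurons with population mean `baseline_rate`;
#'   0 = identical rates). Granule-cell event rates are strongly
#'   right-skewed, and this heterogeneity is what makes simulated
#'   animals differ realistically.
#' @param exclusive_weights assignment probabilities for
#'   `structure = "exclusive"`, names among `place`, `speed`, `direction`,
#'   `none`.
#' @param baseline_rate mean event rate in events/s (default 0.02).
#' @param place_width_range range of place-field widths sigma in cm.
#' @param arena arena dimensions in cm; place centers are drawn inside it.
#' @param seed integer seed.
#' @return a `data.frame` of class `tuning_spec`, one row per neuron, with
#'   attributes `structure` and `arena`.
#' @export
make_tuning_spec <- function(n_neurons = 70,
                             structure = c("independent", "dependent",
                                           "exclusive"),
                             gain_ranges = list(place = c(0, 1),
                                                speed = c(0, 0.3),
                                                direction = c(0, 2),
                                                lr_arm = c(0, 1),
                                                lr_decision = c(0, 1)),
                             exclusive_weights = c(place = 1, speed = 1,
                                                   direction = 1, none = 0),
                             baseline_rate = 0.02,
                             rate_dispersion = 0.7,
                             place_width_range = c(3, 8),
                             arena = c(40, 40),
                             seed = 1L) {
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  structure <- match.arg(structure)
  defaults <- list(place = c(0, 1), speed = c(0, 0.3), direction = c(0, 2),
                   lr_arm = c(0, 1), lr_decision = c(0, 1))
  gain_ranges <- utils::modifyList(defaults, gain_ranges)
  if (baseline_rate < 0) stop("baseline_rate must be nonnegative")

  set.seed(as.integer(seed))
  n <- as.integer(n_neurons)
  rng <- function(u, r) r[1] + u * (r[2] - r[1])

  u <- switch(structure,
    independent = list(place = stats::runif(n), speed = stats::runif(n),
                       direction = stats::runif(n)),
    dependent = {
      shared <- stats::runif(n)
      mix <- function() 0.75 * shared + 0.25 * stats::runif(n)
      list(place = mix(), speed = mix(), direction = mix())
    },
    exclusive = {
      w <- exclusive_weights[c("place", "speed", "direction", "none")]
      w[is.na(w)] <- 0
      if (sum(w) <= 0) stop("exclusive_weights must have positive mass")
      kind <- sample(c("place", "speed", "direction", "none"), n,
                     replace = TRUE, prob = w / sum(w))
      own <- function(type) {
        # graded tuning within the assigned type, zero elsewhere
        ifelse(kind == type, stats::runif(n), 0)
      }
      list(place = own("place"), speed = own("speed"),
           direction = own("direction"))
    })

  base_rates <- if (rate_dispersion > 0) {
    # lognormal with population mean = baseline_rate
    baseline_rate * stats::rlnorm(n, -rate_dispersion^2 / 2, rate_dispersion)
  } else {
    rep(baseline_rate, n)
  }

  spec <- data.frame(
    neuron_id = sprintf("n%03d", seq_len(n)),
    baseline_rate = base_rates,
    place_cx = stats::runif(n, 0, arena[1]),
    place_cy = stats::runif(n, 0, arena[2]),
    place_width = stats::runif(n, place_width_range[1], place_width_range[2]),
    place_gain = rng(u$place, gain_ranges$place),
    speed_slope = rng(u$speed, gain_ranges$speed),
    direction_pref = wrap_angle(stats::runif(n, -pi, pi)),
    direction_kappa = rng(u$direction, gain_ranges$direction),
    lr_arm_pref = sample(c(-1, 1), n, replace = TRUE),
    lr_arm_gain = rng(stats::runif(n), gain_ranges$lr_arm),
    lr_decision_pref = sample(c(-1, 1), n, replace = TRUE),
    lr_decision_gain = rng(stats::runif(n), gain_ranges$lr_decision),
    stringsAsFactors = FALSE
  )
  attr(spec, "structure") <- structure
  attr(spec, "arena") <- as.numeric(arena)
  class(spec) <- c("tuning_spec", "data.frame")
  spec
}

#' @export
print.tuning_spec <- function(x, ...) {
  cat(sprintf("<tuning_spec> %d neurons, structure = %s, mean baseline %.3g Hz\n",
              nrow(x), attr(x, "structure"), mean(x$baseline_rate)))
  invisible(x)
}

#' Serialize a tuning specification to JSON
#'
#' @param spec a [make_tuning_spec()] object.
#' @param path output file.
#' @export
write_tuning_spec_json <- function(spec, path) {
  payload <- list(structure = attr(spec, "structure"),
                  arena = attr(spec, "arena"),
                  neurons = as.data.frame(spec))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a tuning specification from JSON
#'
#' @param path file written by [write_tuning_spec_json()].
#' @return a `tuning_spec` object.
#' @export
read_tuning_spec_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- as.data.frame(payload$neurons, stringsAsFactors = FALSE)
  attr(spec, "structure") <- payload$structure
  attr(spec, "arena") <- as.numeric(payload$arena)
  class(spec) <- c("tuning_spec", "data.frame")
  spec
}
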
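# Ordered-neuron-deletion decoding curves, nine-point pairwise effect
# sizes, the |d| independence matrix, and the two-way ANOVA comparing
# deletion orders.
#
# The logic of the analysis: delete neurons from the dataset one by one
# in a specified order (by decreasing or increasing per-neuron score, or
# at random), retrain the decoder from scratch on the survivors at each
# retention level, and compare how fast performance degrades. If the
# neurons carrying information type A are independent of those carrying
# type B, deleting by decreasing A-score collapses A-decoding quickly
# (large effect size vs random deletion) while deleting by decreasing
# B-score tracks the random curve (small effect size).

parse_order <- function(order_name, scores) {
  if (identical(order_name, "random")) return(list(kind = "random"))
  m <- regmatches(order_name, regexec("^(.*)_(desc|asc)$", order_name))[[1]]
  if (length(m) != 3L || !(m[2] %in% colnames(scores))) {
    stop("unknown deletion order '", order_name,
         "'; expected 'random' or '<score>_desc'/'<score>_asc' with <score> in: ",
         paste(colnames(scores), collapse = ", "))
  }
  list(kind = "scored", score = m[2], decreasing = m[3] == "desc")
}

# Deletion sequence -> retained neuron sets, nested by construction:
# at level k% we keep the last round(n*k/100) neurons of the deletion
# sequence.
retained_set <- function(deletion_seq, level) {
  n <- length(deletion_seq)
  n_keep <- max(1L, round(n * level / 100))
  deletion_seq[(n - n_keep + 1L):n]
}

#' Ordered-deletion decoding curves
#'
#' For every animal, deletion order and retention level, retrains the
#' decoder on the surviving neurons and records out-of-fold performance.
#' The random order is the mean over `n_random` independent permutations
#' per animal. For open-field targets the linear decoder uses
#' precomputed per-fold Gram matrices so each neuron subset costs one
#' small solve; other models retrain generically.
#'
#' @param sessions list of per-animal inputs. For `target` in
#'   position/speed/direction: each element is
#'   `list(recording = , trajectory = )`. For `target = "lr"`: each
#'   element is a [extract_period_activity()] object.
#' @param target `"position"`, `"speed"`, `"direction"` or `"lr"`.
#' @param scores list (one element per animal) of numeric matrices
#'   (neurons x score types, named columns, e.g. `spatial`, `speed`,
#'   `direction`, `lr_arm`) used to rank neurons.
#' @param orders character vector of order names: `"random"` or
#'   `"<score>_desc"` / `"<score>_asc"`.
#' @param levels percent of neurons remaining (default 100, 90, ..., 10).
#' @param model decoder model (`"linear"` recommended here).
#' @param n_random random permutations averaged per animal (default 10).
#' @param window,folds,lambda,hidden decoder settings, as in
#'   [train_and_decode()].
#' @param seed integer seed.
#' @return a `deletion_curves` object: `performance` array
#'   (animals x orders x levels), `target`, `metric_name`, `levels`,
#'   `orders`, `animals`.
#' @export
deletion_curves <- function(sessions, target, scores, orders,
                            levels = seq(100, 10, by = -10),
                            model = "linear", n_random = 10,
                            window = 10L, folds = 5L, lambda = 1,
                            hidden = 64L, seed = 1L) {
  if (length(sessions) != length(scores)) {
    stop("sessions and scores must have one element per animal")
  }
  n_an <- length(sessions)
  perf <- array(NA_real_,
                dim = c(n_an, length(orders), length(levels)),
                dimnames = list(names(sessions) %||%
                                  paste0("animal", seq_len(n_an)),
                                orders, paste0(levels, "%")))

  for (a in seq_len(n_an)) {
    sc <- as.matrix(scores[[a]])
    evaluator <- make_subset_evaluator(sessions[[a]], target, model,
                                       window, folds, lambda, hidden,
                                       seed = derive_seed(seed, a))
    n_neur <- evaluator$n_neurons
    if (nrow(sc) != n_neur) {
      stop("scores for animal ", a, " do not match its neuron count")
    }
    full_perf <- evaluator$eval(seq_len(n_neur))

    for (o in seq_along(orders)) {
      ord <- parse_order(orders[o], sc)
      seqs <- if (ord$kind == "random") {
        lapply(seq_len(n_random), function(r) {
          set.seed(as.integer(derive_seed(seed, a * 1000L + r)))
          sample.int(n_neur)
        })
      } else {
        list(order(sc[, ord$score], decreasing = ord$decreasing))
      }
      for (l in seq_along(levels)) {
        if (levels[l] >= 100) {
          perf[a, o, l] <- full_perf  # full population: order-independent
          next
        }
        perf[a, o, l] <- mean(vapply(
          seqs, function(s) evaluator$eval(retained_set(s, levels[l])),
          numeric(1)))
      }
    }
  }

  structure(list(performance = perf, target = target,
                 metric_name = metric_name_for(target),
                 levels = levels, orders = orders,
                 animals = dimnames(perf)[[1]]),
            class = "deletion_curves")
}

# Returns an object with $eval(neuron_set) -> metric, retraining the
# decoder on the given neurons only.
make_subset_evaluator <- function(session, target, model, window, folds,
                                  lambda, hidden, seed) {
  if (target == "lr") {
    stopifnot(inherits(session, "period_activity"))
    n_neur <- ncol(session$counts)
    ev <- function(neurons) {
      sub <- session
      sub$counts <- session$counts[, neurons, drop = FALSE]
      sub$neuron_ids <- session$neuron_ids[neurons]
      decode_lr(sub, model = if (model == "linear") "linear" else model,
                lambda = lambda, seed = seed)$metric
    }
    return(list(eval = ev, n_neurons = n_neur))
  }

  events <- if (inherits(session$recording, "population_recording"))
    session$recording$events else session$recording
  trajectory <- session$trajectory
  n_neur <- ncol(events)

  if (model != "linear") {
    ev <- function(neurons) {
      train_and_decode(events[, neurons, drop = FALSE], trajectory,
                       target = target, model = model, window = window,
                       folds = folds, lambda = lambda, hidden = hidden,
                       seed = seed)$metric
    }
    return(list(eval = ev, n_neurons = n_neur))
  }

  # linear fast path: one Gram per fold, subset by neuron columns
  tg <- decoding_targets(trajectory, target)
  X <- build_features(events, window)
  n <- nrow(X)
  fold_id <- contiguous_folds(n, folds)
  stats_f <- vector("list", folds)
  test_sets <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- fold_id != f & tg$valid
    test_sets[[f]] <- which(fold_id == f & tg$valid)
    stats_f[[f]] <- fold_stats(X, tg$Y, train)
  }
  frames <- which(tg$valid)
  obs <- if (target == "position") tg$obs[frames, , drop = FALSE]
         else tg$obs[frames]

  ev <- function(neurons) {
    cols <- neuron_columns(neurons, n_neur, window)
    pred_raw <- matrix(NA_real_, n, ncol(tg$Y))
    for (f in seq_len(folds)) {
      st <- stats_f[[f]]
      B <- ridge_coef(st$Gc[cols, cols, drop = FALSE],
                      st$Ac[cols, , drop = FALSE], lambda)
      te <- test_sets[[f]]
      if (!length(te)) next
      pred_raw[te, ] <- ridge_predict(st, B, X[te, cols, drop = FALSE],
                                      cols = cols)
    }
    predictions <- switch(target,
      position = pred_raw[frames, , drop = FALSE],
      speed = pred_raw[frames, 1],
      direction = atan2(pred_raw[frames, 1], pred_raw[frames, 2]))
    res <- structure(list(target = target, predictions = predictions,
                          observed = obs),
                     class = "decoding_result")
    evaluate(res)
  }
  list(eval = ev, n_neurons = n_neur)
}

#' Assemble a deletion_curves object from a performance array
#'
#' Useful for building curve sets from externally computed performances
#' (and for testing the statistical layer in isolation).
#'
#' @param performance 3-d array, animals x orders x levels.
#' @param orders,levels dimension labels.
#' @param target,metric_name metadata strings.
#' @return a `deletion_curves` object.
#' @export
as_deletion_curves <- function(performance, orders, levels,
                               target = "position",
                               metric_name = "metric") {
  stopifnot(length(dim(performance)) == 3L,
            dim(performance)[2] == length(orders),
            dim(performance)[3] == length(levels))
  dimnames(performance) <- list(
    dimnames(performance)[[1]] %||%
      paste0("animal", seq_len(dim(performance)[1])),
    orders, paste0(levels, "%"))
  structure(list(performance = performance, target = target,
                 metric_name = metric_name, levels = levels,
                 orders = orders, animals = dimnames(performance)[[1]]),
            class = "deletion_curves")
}

#' @export
print.deletion_curves <- function(x, ...) {
  cat(sprintf("<deletion_curves> %s (%s): %d animals x %d orders x %d levels\n",
              x$target, x$metric_name, dim(x$performance)[1],
              dim(x$performance)[2], dim(x$performance)[3]))
  invisible(x)
}

#' Nine-point effect size between two deletion orders
#'
#' Cohen's d (pooled SD, across animals) between two orders' decoding
#' performances at each of the nine retention levels 90..10%, plus the
#' mean absolute d over the nine points — the entry of the independence
#' matrix.
#'
#' @param curves a `deletion_curves` object.
#' @param order_a,order_b order names present in `curves`.
#' @param points retention levels at which d is computed (default
#'   90, 80, ..., 10).
#' @return list with `d` (named vector over points), `mean_abs_d`.
#' @export
pairwise_effect_size <- function(curves, order_a, order_b,
                                 points = seq(90, 10, by = -10)) {
  stopifnot(inherits(curves, "deletion_curves"))
  if (dim(curves$performance)[1] < 2L) {
    stop("effect sizes need at least 2 animals")
  }
  ia <- match(order_a, curves$orders)
  ib <- match(order_b, curves$orders)
  if (is.na(ia) || is.na(ib)) stop("order not found in curves")
  il <- match(points, curves$levels)
  if (any(is.na(il))) stop("requested levels not present in curves")
  d <- vapply(il, function(l) {
    cohens_d(curves$performance[, ia, l], curves$performance[, ib, l])
  }, numeric(1))
  d[!is.finite(d)] <- 0  # identical zero-variance curves
  names(d) <- paste0(points, "%")
  list(d = d, mean_abs_d = mean(abs(d)))
}

#' Pairwise |d| independence matrix over deletion orders
#'
#' @param curves a `deletion_curves` object with >= 2 orders.
#' @param points retention levels used per pair (default 90..10%).
#' @return symmetric matrix of mean |Cohen's d| with zero diagonal,
#'   class `effect_size_matrix`.
#' @export
effect_size_matrix <- function(curves, points = seq(90, 10, by = -10)) {
  stopifnot(inherits(curves, "deletion_curves"))
  k <- length(curves$orders)
  if (k < 2L) stop("need at least 2 orders")
  m <- matrix(0, k, k, dimnames = list(curves$orders, curves$orders))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      v <- pairwise_effect_size(curves, curves$orders[i],
                                curves$orders[j], points)$mean_abs_d
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, class = c("effect_size_matrix", "matrix"))
}

#' Two-way ANOVA comparing deletion orders
#'
#' Performances are averaged over animals to one value per order x level
#' cell, then analysed with a two-way ANOVA (factors: deletion order and
#' percent of cells remaining, no interaction), matching the F(k-1,
#' (k-1)(L-1)) design reported for these curves; Tukey HSD post hoc
#' contrasts compare orders (Tukey-Kramer adjusted).
#'
#' @param curves a `deletion_curves` object (balanced: no missing cells).
#' @return list with `order_F`, `order_df` (c(df1, df2)), `order_p`,
#'   `level_F`, `level_p`, `posthoc` (Tukey table for the order factor),
#'   `fit`.
#' @export
compare_orders_anova <- function(curves) {
  stopifnot(inherits(curves, "deletion_curves"))
  perf <- curves$performance
  if (any(is.na(perf))) stop("unbalanced design: missing performances")
  cell <- apply(perf, c(2, 3), mean)  # orders x levels, mean over animals
  df <- data.frame(
    perf = as.vector(cell),
    order = factor(rep(curves$orders, times = length(curves$levels))),
    level = factor(rep(curves$levels, each = length(curves$orders))))
  fit <- stats::aov(perf ~ order + level, data = df)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  # degenerate case: identical curves make both the order and residual
  # sums of squares exactly zero; report F = 0 rather than 0/0 noise
  ss_tot <- sum(tab[, "Sum Sq"])
  if (tab["order", "Sum Sq"] <= 1e-12 * max(ss_tot, .Machine$double.xmin)) {
    tab["order", "F value"] <- 0
    tab["order", "Pr(>F)"] <- 1
  }
  posthoc <- tryCatch(stats::TukeyHSD(fit, "order")$order,
                      error = function(e) NULL)
  list(order_F = tab["order", "F value"],
       order_df = c(tab["order", "Df"], tab["Residuals", "Df"]),
       order_p = tab["order", "Pr(>F)"],
       level_F = tab["level", "F value"],
       level_p = tab["level", "Pr(>F)"],
       posthoc = posthoc,
       fit = fit)
}
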
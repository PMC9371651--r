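#!/usr/bin/env Rscript
# Per-neuron tuning and information analysis of the open-field cohort:
# spatial/speed/direction tuning summaries, Skaggs information with
# 1,000-shuffle circular-shift nulls, per-neuron 95th-percentile
# significance, the population permutation test with Cohen's d, and the
# pairwise information scatter correlations.
# Requires: analysis/01_simulate_cohorts.R

suppressMessages(library(dgcoding))
out_dir <- "results/information"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

animals <- sprintf("results/cohorts/of_animal%02d", 1:7)
stopifnot(all(dir.exists(animals)))

per_neuron <- list()
pop_rows <- list()
for (a in seq_along(animals)) {
  dat <- read_recording(file.path(animals[a], "events.csv"),
                        file.path(animals[a], "trajectory.csv"),
                        arena = c(40, 40))
  st <- discretize_states(compute_kinematics(dat$trajectory),
                          dat$trajectory)
  labels <- list(spatial = st$position_bin, speed = st$speed_class,
                 direction = st$direction_bin)
  dt <- 1 / dat$recording$frame_rate
  for (v in names(labels)) {
    res <- lapply(seq_len(ncol(dat$recording$events)), function(j) {
      info_result(dat$recording$events[, j], labels[[v]], dt,
                  n_shuffles = 1000, seed = 1000 * a + j)
    })
    pt <- population_info_test(res, seed = 10 + a)
    pop_rows[[paste(a, v)]] <- data.frame(
      animal = a, variable = v, p_value = pt$p_value,
      cohens_d = pt$cohens_d, frac_above_p95 = pt$frac_above_p95)
    per_neuron[[paste(a, v)]] <- data.frame(
      animal = a, variable = v,
      neuron_id = dat$recording$neuron_ids,
      info_bits = vapply(res, function(r) as.numeric(r$info), 1),
      null_p95 = vapply(res, function(r) r$null_p95, 1),
      exceeds = vapply(res, function(r) r$exceeds_p95, NA),
      percentile = vapply(res, function(r) r$percentile, 1))
  }
  # representative tuning summaries for one neuron per animal
  m <- spatial_tuning_map(dat$recording, dat$trajectory, sigma = 2,
                          neuron = 1)
  utils::write.csv(m$normalized,
                   file.path(out_dir, sprintf("map_animal%02d_n1.csv", a)),
                   row.names = FALSE)
}
per_neuron <- do.call(rbind, per_neuron)
pop <- do.call(rbind, pop_rows)
utils::write.csv(per_neuron, file.path(out_dir, "per_neuron_info.csv"),
                 row.names = FALSE)
utils::write.csv(pop, file.path(out_dir, "population_tests.csv"),
                 row.names = FALSE)

# pairwise information correlations across all neurons (pooled animals)
wide <- reshape(per_neuron[, c("animal", "neuron_id", "variable",
                               "info_bits")],
                idvar = c("animal", "neuron_id"), timevar = "variable",
                direction = "wide")
names(wide) <- sub("info_bits.", "", names(wide))
pairs <- combn(c("spatial", "speed", "direction"), 2)
corr <- apply(pairs, 2, function(p) {
  cor(wide[[p[1]]], wide[[p[2]]], use = "complete.obs")
})
corr_tab <- data.frame(pair = apply(pairs, 2, paste, collapse = "_x_"),
                       r = corr)
utils::write.csv(corr_tab, file.path(out_dir, "info_correlations.csv"),
                 row.names = FALSE)

cat("population tests (per animal x variable):\n")
print(pop, row.names = FALSE)
cat("\npairwise information correlations (pooled neurons):\n")
print(corr_tab, row.names = FALSE)
cat(sprintf("\n%d neurons analysed; results under %s\n",
            nrow(wide), out_dir))
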
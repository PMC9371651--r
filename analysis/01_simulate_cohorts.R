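#!/usr/bin/env Rscript
# Simulates the study's two synthetic cohorts and writes them to disk:
#   - open field: 7 animals x 70 neurons, 30-min sessions at 3 Hz,
#     mixed-selective independent tuning, ~0.02 Hz mean event rate;
#   - T-maze: 7 animals, 50 forced-alternation trials each, 71.4%
#     correct alternation, LR-tuned neurons.
# Downstream scripts (02-05) reload these CSV/JSON files.

suppressMessages(library(dgcoding))
set.seed(1)
out_root <- "results/cohorts"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

n_animals <- 7
for (a in seq_len(n_animals)) {
  tr <- simulate_of_trajectory(duration_s = 1800, frame_rate = 3,
                               seed = 100 + a)
  spec <- make_tuning_spec(70, structure = "independent", seed = 200 + a)
  rec <- generate_events(tr, spec, seed = 300 + a)
  dir_of <- file.path(out_root, sprintf("of_animal%02d", a))
  write_recording(rec, tr, dir_of)
  write_tuning_spec_json(spec, file.path(dir_of, "tuning_spec.json"))

  ss <- simulate_tmaze_session(50, correct_rate = 0.714, spec = spec,
                               seed = 400 + a)
  dir_tm <- file.path(out_root, sprintf("tmaze_animal%02d", a))
  dir.create(dir_tm, showWarnings = FALSE)
  write_trials_csv(ss$trials, file.path(dir_tm, "trials.csv"))
  write_events_csv(ss$recording, file.path(dir_tm, "events.csv"))
  write_trajectory_csv(ss$trajectory, file.path(dir_tm, "trajectory.csv"))

  cat(sprintf(
    "animal %d: OF mean rate %.4f Hz; T-maze correct %.0f%% (%d trials)\n",
    a, mean_event_rate(rec), correct_choice_rate(ss), nrow(ss$trials)))
}
cat("cohorts written under", out_root, "\n")
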
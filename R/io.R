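# File formats and dF/F event detection.
#
# CSV is the canonical interchange format. Schemas:
#   trajectory: time_s, x_cm, y_cm            (+ attributes in the header
#               are not used; arena inferred or passed explicitly)
#   events:     frames x neurons 0/1 matrix, header row of neuron IDs
#   trials:     trial_id, forced_side, free_choice, correct,
#               forced_turn_time_s, free_choice_turn_time_s
# All lengths in cm, times in seconds, angles in radians ((-pi, pi],
# north = 0).

#' Detect calcium events in a dF/F trace
#'
#' Candidate onsets are upward crossings of `median + threshold_factor *
#' MAD` (unscaled median absolute deviation). A candidate is accepted
#' only if, after the within-excursion peak, the trace stays above
#' threshold for at least `min_decay_s` — transients that collapse
#' faster than a GCaMP decay are treated as noise. One event is marked
#' at each accepted onset frame. Defaults are the standard settings for
#' this detector (threshold 4 MADs, shortest decay 0.2 s).
#'
#' @param dff numeric dF/F trace.
#' @param frame_rate sampling rate of the trace (Hz).
#' @param threshold_factor threshold in MADs above the median.
#' @param min_decay_s minimum post-peak time above threshold (s).
#' @return integer 0/1 event train, same length as `dff`.
#' @export
detect_events <- function(dff, frame_rate, threshold_factor = 4,
                          min_decay_s = 0.2) {
  if (any(!is.finite(dff))) stop("dF/F trace must be finite")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  out <- integer(length(dff))
  m <- stats::median(dff)
  s <- stats::mad(dff, constant = 1)
  if (s == 0) {
    warning("constant trace (MAD = 0); no events detected")
    return(out)
  }
  thr <- m + threshold_factor * s
  above <- dff > thr
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    run <- starts[k]:ends[k]
    peak <- run[which.max(dff[run])]
    decay_s <- (ends[k] - peak) / frame_rate
    if (decay_s >= min_decay_s) out[starts[k]] <- 1L
  }
  out
}

#' Write / read a trajectory as CSV
#'
#' Columns `time_s`, `x_cm`, `y_cm`. The arena size and frame rate are
#' re-derived on read (`arena` can be overridden).
#'
#' @param trajectory a `trajectory` object.
#' @param path CSV file path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(data.frame(time_s = trajectory$time_s,
                              x_cm = trajectory$x_cm,
                              y_cm = trajectory$y_cm),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param arena arena dimensions in cm; defaults to the data's ceiling.
#' @return `read_trajectory_csv`: a `trajectory` object.
#' @export
read_trajectory_csv <- function(path, arena = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "x_cm", "y_cm")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  }
  dts <- diff(df$time_s)
  if (any(dts <= 0)) stop("trajectory times must be strictly increasing")
  rate <- 1 / stats::median(dts)
  arena <- arena %||% c(max(df$x_cm), max(df$y_cm))
  structure(list(time_s = df$time_s, x_cm = df$x_cm, y_cm = df$y_cm,
                 frame_rate = rate, arena = as.numeric(arena),
                 duration_s = length(df$time_s) / rate),
            class = "trajectory")
}

#' Write / read a population event matrix as CSV
#'
#' Frames x neurons 0/1 matrix with a header row of neuron IDs.
#'
#' @param recording a `population_recording`.
#' @param path CSV file path.
#' @export
write_events_csv <- function(recording, path) {
  utils::write.csv(as.data.frame(recording$events), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param frame_rate frames per second of the stored trains.
#' @return `read_events_csv`: a `population_recording`.
#' @export
read_events_csv <- function(path, frame_rate = 3) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- names(df)
  if (anyDuplicated(ids)) {
    stop("duplicate neuron IDs in events CSV: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df)
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("non-binary event value at row %d, column '%s'",
                 rc[1], ids[rc[2]]))
  }
  new_population_recording(m, ids, frame_rate)
}

#' Write / read a T-maze trial table as CSV
#'
#' @param trials the `trials` data frame of a `tmaze_session`.
#' @param path CSV file path.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials[, c("trial_id", "forced_side", "free_choice",
                              "correct", "forced_turn_time_s",
                              "free_choice_turn_time_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @return `read_trials_csv`: the trial table, validated.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial_id", "forced_side", "free_choice", "correct",
            "forced_turn_time_s", "free_choice_turn_time_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trial CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(df$forced_side %in% c("L", "R")) ||
      !all(df$free_choice %in% c("L", "R"))) {
    stop("trial sides must be 'L' or 'R'")
  }
  df$correct <- as.logical(df$correct)
  if (!all(df$correct == (df$free_choice != df$forced_side))) {
    stop("correct flag inconsistent with forced/free sides")
  }
  df
}

#' Read an aligned recording + trajectory pair
#'
#' Loads both files and validates that the event trains and the
#' trajectory have the same number of frames.
#'
#' @param events_path events CSV (see [write_events_csv()]).
#' @param trajectory_path trajectory CSV (see [write_trajectory_csv()]).
#' @param arena optional arena dimensions passed to
#'   [read_trajectory_csv()].
#' @return list with `recording` and `trajectory`.
#' @export
read_recording <- function(events_path, trajectory_path, arena = NULL) {
  trajectory <- read_trajectory_csv(trajectory_path, arena = arena)
  recording <- read_events_csv(events_path,
                               frame_rate = trajectory$frame_rate)
  if (nrow(recording$events) != n_frames(trajectory)) {
    stop(sprintf(
      "alignment error: %d event frames vs %d trajectory frames",
      nrow(recording$events), n_frames(trajectory)))
  }
  list(recording = recording, trajectory = trajectory)
}

#' Write an aligned recording + trajectory pair to a directory
#'
#' Writes `events.csv` and `trajectory.csv` under `dir`.
#'
#' @param recording a `population_recording`.
#' @param trajectory the aligned `trajectory`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_recording <- function(recording, trajectory, dir) {
  if (nrow(recording$events) != n_frames(trajectory)) {
    stop("recording and trajectory differ in frame count")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_events_csv(recording, file.path(dir, "events.csv"))
  write_trajectory_csv(trajectory, file.path(dir, "trajectory.csv"))
  invisible(dir)
}
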
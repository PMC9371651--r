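# Kinematics and behavioural-state discretization.
#
# Conventions (fixed throughout the package): x increases east, y
# increases north; motion direction is atan2(-dx, dy), so north = 0,
# west spans (0, pi), east spans (0, -pi). Speed classes are 0-1, 1-5 and
# >5 cm/s; motion direction is discretized into 8 arcs of width pi/4
# centered on 0, +/-pi/4, +/-pi/2, +/-3pi/4 and pi.

#' Compute speed and motion direction from a trajectory
#'
#' Positions are optionally smoothed with a centered moving average (the
#' default 3-frame window is 1 s at 3 Hz, suppressing tracking jitter)
#' and then differentiated frame to frame. Frame t carries the
#' displacement from frame t-1 to t; frame 1 inherits the speed of frame
#' 2 and has no direction. Direction is undefined (flagged invalid)
#' wherever the displacement is zero.
#'
#' @param trajectory a `trajectory` object.
#' @param smoothing_window moving-average window in frames (odd; 1 = no
#'   smoothing).
#' @return a `data.frame` with columns `speed` (cm/s), `direction`
#'   (radians in (-pi, pi], north = 0, west positive) and
#'   `valid_direction`.
#' @export
compute_kinematics <- function(trajectory, smoothing_window = 3L) {
  stopifnot(inherits(trajectory, "trajectory"))
  n <- n_frames(trajectory)
  if (n < 2L) stop("compute_kinematics() needs at least 2 frames")
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L) stop("smoothing_window must be a positive odd integer")

  x <- trajectory$x_cm
  y <- trajectory$y_cm
  if (w > 1L && n > w) {
    x <- moving_average(x, w)
    y <- moving_average(y, w)
  }
  dt <- diff(trajectory$time_s)
  dx <- diff(x)
  dy <- diff(y)
  disp <- sqrt(dx^2 + dy^2)
  speed <- c(NA_real_, disp / dt)
  speed[1] <- speed[2]
  moved <- disp > 0
  direction <- c(NA_real_, ifelse(moved, atan2(-dx, dy), NA_real_))
  valid <- c(FALSE, moved)

  data.frame(speed = speed,
             direction = wrap_angle(direction),
             valid_direction = valid)
}

# centered moving average with shrinking windows at the ends
moving_average <- function(v, w) {
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Speed-class boundaries (cm/s)
#'
#' The three behavioural speed classes: \[0,1), \[1,5), \[5, Inf).
#' @export
speed_class_breaks <- c(0, 1, 5, Inf)

#' Discretize behaviour into position, speed and direction bins
#'
#' Position bins form an equal-area `grid` over the arena (half-open
#' cells; the last row/column is closed so boundary points belong to the
#' arena). Speed classes are \[0,1), \[1,5), \[5,Inf) cm/s. Direction bins
#' are 8 arcs of width pi/4; bin k (1-based) is centered on
#' `(k-1) * pi/4` wrapped to (-pi, pi], so bin 1 = north, bins 2-4 sweep
#' west, bin 5 = south, bins 6-8 sweep east.
#'
#' @param kin output of [compute_kinematics()].
#' @param trajectory the matching `trajectory`.
#' @param grid `c(rows, cols)` of the spatial occupancy grid (default
#'   10 x 10).
#' @return a `data.frame` with `pos_row`, `pos_col`, `position_bin`
#'   (1..rows*cols, row-major), `speed_class` (1..3), `direction_bin`
#'   (1..8, NA where direction invalid), `valid_direction`.
#' @export
discretize_states <- function(kin, trajectory, grid = c(10L, 10L)) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (length(grid) != 2L || any(grid < 2L)) stop("grid must be at least 2 x 2")
  if (nrow(kin) != n_frames(trajectory)) {
    stop("kinematics and trajectory differ in frame count")
  }
  arena <- trajectory$arena
  x <- trajectory$x_cm
  y <- trajectory$y_cm
  if (any(x < 0 | x > arena[1] | y < 0 | y > arena[2])) {
    stop("trajectory leaves the arena; cannot assign position bins")
  }
  col <- pmin(floor(x / (arena[1] / grid[2])), grid[2] - 1L) + 1L
  row <- pmin(floor(y / (arena[2] / grid[1])), grid[1] - 1L) + 1L
  position_bin <- (row - 1L) * grid[2] + col

  speed_class <- findInterval(kin$speed, speed_class_breaks,
                              rightmost.closed = FALSE)
  speed_class[speed_class > 3L] <- 3L

  direction_bin <- ifelse(kin$valid_direction,
                          (round(kin$direction / (pi / 4)) %% 8) + 1L,
                          NA_integer_)

  out <- data.frame(pos_row = as.integer(row),
                    pos_col = as.integer(col),
                    position_bin = as.integer(position_bin),
                    speed_class = as.integer(speed_class),
                    direction_bin = as.integer(direction_bin),
                    valid_direction = kin$valid_direction)
  attr(out, "grid") <- as.integer(grid)
  out
}
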
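#' Centered moving average with shrunken edge windows
#'
#' Position (and velocity) series are smoothed with a moving average before
#' differentiation, to reduce noise amplification. The window is centered;
#' with an even window of `w` frames it spans frames `[t - w/2, t + w/2 - 1]`.
#' At the series edges the window is clipped to the available samples, so the
#' output has the same length as the input.
#'
#' @param x Numeric vector.
#' @param window_frames Window size in samples; default 18 frames (0.6 s at
#'   30 Hz).
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window_frames = 18) {
  n <- length(x)
  w <- as.integer(window_frames)
  if (w < 1) stop("window must be >= 1")
  if (w > n) stop("window larger than series")
  half_lo <- floor(w / 2)         # frames before t
  half_hi <- w - half_lo - 1      # frames after t
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  lo <- pmax(1, idx - half_lo)
  hi <- pmin(n, idx + half_hi)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

smooth_xyz <- function(traj, window_frames = 18) {
  cbind(moving_average(traj$x_cm, window_frames),
        moving_average(traj$y_cm, window_frames),
        moving_average(traj$z_cm, window_frames))
}

velocity_xyz <- function(pos, dt) {
  apply(pos, 2, diff) / dt
}

#' Kinematic series: speed, acceleration magnitude, turn rate
#'
#' Speed is the norm of the first difference of the (smoothed) positions
#' divided by the frame interval; acceleration magnitude is the norm of the
#' first difference of the (smoothed) velocities. The turn rate at step t is
#' the angle between consecutive velocity vectors divided by the frame
#' interval, `acos(v_t . v_{t+1} / (|v_t| |v_{t+1}|)) / dt` (rad/s), with the
#' cosine clamped to `[-1, 1]`; steps where either velocity is essentially
#' zero yield `NA` (the angle is undefined).
#'
#' @param traj Trajectory data frame with `t_s`, `x_cm`, `y_cm`, `z_cm`.
#' @param smooth_window Moving-average window applied to positions (and, for
#'   the acceleration, to velocities); `0` disables smoothing.
#' @return Numeric vector (one element per frame interval).
#' @export
speed_series <- function(traj, smooth_window = 18) {
  dt <- traj$t_s[2] - traj$t_s[1]
  pos <- if (smooth_window > 0) smooth_xyz(traj, smooth_window)
         else as.matrix(traj[, c("x_cm", "y_cm", "z_cm")])
  v <- velocity_xyz(pos, dt)
  sqrt(rowSums(v^2))
}

#' @rdname speed_series
#' @export
accel_series <- function(traj, smooth_window = 18) {
  dt <- traj$t_s[2] - traj$t_s[1]
  pos <- if (smooth_window > 0) smooth_xyz(traj, smooth_window)
         else as.matrix(traj[, c("x_cm", "y_cm", "z_cm")])
  v <- velocity_xyz(pos, dt)
  if (smooth_window > 0) v <- apply(v, 2, moving_average, smooth_window)
  a <- apply(v, 2, diff) / dt
  sqrt(rowSums(a^2))
}

#' @rdname speed_series
#' @export
turn_rate_series <- function(traj, smooth_window = 18) {
  dt <- traj$t_s[2] - traj$t_s[1]
  pos <- if (smooth_window > 0) smooth_xyz(traj, smooth_window)
         else as.matrix(traj[, c("x_cm", "y_cm", "z_cm")])
  v <- velocity_xyz(pos, dt)
  n <- nrow(v)
  v1 <- v[-n, , drop = FALSE]
  v2 <- v[-1, , drop = FALSE]
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  cosang <- rowSums(v1 * v2) / (n1 * n2)
  cosang <- pmin(1, pmax(-1, cosang))
  out <- acos(cosang) / dt
  out[n1 < 1e-6 | n2 < 1e-6] <- NA_real_
  out
}

# Observation-window subset of a trajectory (last observation_s seconds).
observation_window <- function(trial, traj) {
  traj[traj$t_s > trial$habituation_s, , drop = FALSE]
}

#' Avoidance metrics
#'
#' Two per-trial avoidance measures over the observation window: the average
#' fish-replica distance (for the control condition the reference point is
#' the geometric center of the lateral tank's water volume), and the
#' percentage of time the fish spends in the vertical half of the water
#' column opposite the one occupied by the replica.
#'
#' @param trial A `trial_record`.
#' @return List with `avg_distance_cm` and `pct_time_opposite_half` (the
#'   latter `NA` for the control condition, where no replica is present).
#' @export
avoidance_metrics <- function(trial) {
  fish <- observation_window(trial, trial$fish_traj)
  robot <- observation_window(trial, trial$robot_traj)
  d <- sqrt((fish$x_cm - robot$x_cm)^2 + (fish$y_cm - robot$y_cm)^2 +
              (fish$z_cm - robot$z_cm)^2)
  mid <- trial$arena$water_depth_cm / 2
  opposite <- if (trial$condition == "control") NA_real_ else
    100 * mean((fish$z_cm <= mid) != (robot$z_cm <= mid))
  list(avg_distance_cm = mean(d), pct_time_opposite_half = opposite)
}

#' Geotaxis metrics
#'
#' Bottom-dwelling measures over the observation window: average height above
#' the tank base, percentage of time in the bottom section (by default the
#' bottom third of the water column), and the number of entries into the
#' bottom section (downward crossings of its boundary between consecutive
#' smoothed samples).
#'
#' @param trial A `trial_record`.
#' @param bottom_cm Height of the bottom section; defaults to one third of
#'   the water depth (5 cm at the default 15 cm depth).
#' @param smooth_window Moving-average window used for the entry count.
#' @return List with `avg_height_cm`, `pct_time_bottom`, `n_entries_bottom`.
#' @export
geotaxis_metrics <- function(trial, bottom_cm = trial$arena$water_depth_cm / 3,
                             smooth_window = 18) {
  fish <- observation_window(trial, trial$fish_traj)
  z <- fish$z_cm
  zs <- if (smooth_window > 0) moving_average(z, smooth_window) else z
  inside <- zs < bottom_cm
  entries <- sum(!inside[-length(inside)] & inside[-1])
  list(avg_height_cm = mean(z),
       pct_time_bottom = 100 * mean(inside),
       n_entries_bottom = as.integer(entries))
}

#' Replica occupancy measures
#'
#' Percentage of observation time the replica spends in the lower half of the
#' water column, and percentage of time in the attacking state. Undefined
#' (NA) for the control condition.
#'
#' @param trial A `trial_record`.
#' @return List with `pct_robot_lower_half` and `pct_robot_attacking`.
#' @export
robot_occupancy <- function(trial) {
  if (trial$condition == "control")
    return(list(pct_robot_lower_half = NA_real_,
                pct_robot_attacking = NA_real_))
  robot <- observation_window(trial, trial$robot_traj)
  states <- trial$robot_states[(trial$habituation_s + 1):
                                 (trial$habituation_s + trial$observation_s)]
  mid <- trial$arena$water_depth_cm / 2
  list(pct_robot_lower_half = 100 * mean(robot$z_cm <= mid),
       pct_robot_attacking = 100 * mean(states == "A"))
}

#' Time-weighted means of a metric series over 2-min bins
#'
#' Splits the 6-min observation window into three 2-min bins (0-2, 2-4,
#' 4-6 min) and averages the series within each bin.
#'
#' @param values Numeric series covering the observation window.
#' @param t_s Time stamps of `values`, seconds from observation start
#'   (exclusive of 0); defaults to a uniform grid over `observation_s`.
#' @param observation_s Observation duration, seconds.
#' @param bin_s Bin width, seconds.
#' @return Named numeric vector, one element per bin.
#' @export
bin_by_time <- function(values, t_s = NULL, observation_s = 360, bin_s = 120) {
  if (is.null(t_s))
    t_s <- seq_along(values) / length(values) * observation_s
  edges <- seq(0, observation_s, by = bin_s)
  bin <- cut(t_s, breaks = edges, include.lowest = TRUE)
  out <- tapply(values, bin, mean, na.rm = TRUE)
  names(out) <- sprintf("%d-%d min", utils::head(edges, -1) / 60,
                        utils::tail(edges, -1) / 60)
  out
}

#' Per-trial, per-bin metric table
#'
#' Computes the nine dependent measures (two avoidance, three geotaxis, three
#' activity, plus the two replica occupancy measures) for each 2-min bin of
#' the observation window, returning one row per bin in tidy form.
#'
#' @param trial A `trial_record`.
#' @param trial_id Identifier copied into the output rows.
#' @param smooth_window Moving-average window for the kinematic series.
#' @return Data frame with one row per time bin.
#' @export
trial_metrics <- function(trial, trial_id = trial$seed, smooth_window = 18) {
  fish <- observation_window(trial, trial$fish_traj)
  robot <- observation_window(trial, trial$robot_traj)
  obs_s <- trial$observation_s
  t_rel <- fish$t_s - trial$habituation_s
  mid <- trial$arena$water_depth_cm / 2
  bottom <- trial$arena$water_depth_cm / 3

  dist <- sqrt((fish$x_cm - robot$x_cm)^2 + (fish$y_cm - robot$y_cm)^2 +
                 (fish$z_cm - robot$z_cm)^2)
  opp <- if (trial$condition == "control") rep(NA_real_, nrow(fish)) else
    100 * ((fish$z_cm <= mid) != (robot$z_cm <= mid))
  zs <- moving_average(fish$z_cm, smooth_window)
  inside <- zs < bottom
  sp <- speed_series(fish, smooth_window)
  ac <- accel_series(fish, smooth_window)
  tr <- turn_rate_series(fish, smooth_window)
  states_obs <- trial$robot_states[(trial$habituation_s + 1):
                                     (trial$habituation_s + obs_s)]

  nbin <- obs_s / 120
  bins <- sprintf("%d-%d min", 2 * (seq_len(nbin) - 1), 2 * seq_len(nbin))
  rows <- lapply(seq_len(nbin), function(b) {
    sel <- t_rel > (b - 1) * 120 & t_rel <= b * 120
    # series from diff() are one element shorter; align to interval starts
    seld <- utils::head(sel, length(sp))
    seldd <- utils::head(sel, length(ac))
    ins <- inside[sel]
    entries <- sum(!ins[-length(ins)] & ins[-1])
    sel_s <- seq_len(obs_s) > (b - 1) * 120 & seq_len(obs_s) <= b * 120
    data.frame(
      trial_id = trial_id, condition = trial$condition, time_bin = bins[b],
      avg_distance_to_replica_cm = mean(dist[sel]),
      pct_time_opposite_half = mean(opp[sel]),
      avg_height_cm = mean(fish$z_cm[sel]),
      pct_time_bottom_third = 100 * mean(ins),
      n_entries_bottom = as.integer(entries),
      avg_speed_cm_s = mean(sp[seld]),
      avg_accel_mag_cm_s2 = mean(ac[seldd]),
      avg_turn_rate_rad_s = mean(tr[utils::head(sel, length(tr))], na.rm = TRUE),
      pct_robot_lower_half = if (trial$condition == "control") NA_real_ else
        100 * mean(robot$z_cm[sel] <= mid),
      pct_robot_attacking = if (trial$condition == "control") NA_real_ else
        100 * mean(states_obs[sel_s] == "A"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
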
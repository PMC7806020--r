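#' Generate an open-loop behavior schedule
#'
#' Simulates a 1 Hz behavior-state sequence from the three-state open-loop
#' chain, starting from the stationary state. The published experiment used
#' 20-min simulations of 1,200 events to drive the replica in open loop.
#'
#' @param M_OL Three-state [transition_matrix()] over (St, Sw, A).
#' @param duration_s Number of 1 Hz events to generate.
#' @return Character vector of length `duration_s`, first element `"St"`.
#' @export
generate_open_loop_schedule <- function(M_OL, duration_s) {
  duration_s <- as.integer(duration_s)
  stopifnot(duration_s >= 1, nrow(M_OL) == 3)
  states <- rownames(M_OL)
  P <- unclass(M_OL)
  out <- character(duration_s)
  out[1] <- "St"
  i <- match("St", states)
  if (duration_s > 1) {
    u <- stats::runif(duration_s - 1)
    cum <- t(apply(P, 1, cumsum))
    for (t in 2:duration_s) {
      i <- which(u[t - 1] <= cum[i, ])[1]
      out[t] <- states[i]
    }
  }
  out
}

#' One closed-loop behavior transition
#'
#' Given the replica's current behavior and the fish's current proximity
#' class, draws the replica's next behavior from the corresponding row of the
#' six-state joint chain and discards the proximity component (the actual
#' proximity at the next step is determined by where the fish really is).
#'
#' @param M_CL Six-state joint [transition_matrix()].
#' @param current_behavior `"St"`, `"Sw"` or `"A"`.
#' @param proximity `"C"` or `"F"`.
#' @return Next behavior state label.
#' @export
step_closed_loop <- function(M_CL, current_behavior, proximity) {
  nxt <- sample_next_state(M_CL, paste(current_behavior, proximity, sep = "-"))
  sub("-.*$", "", nxt)
}

# --- replica movement -------------------------------------------------------

# Internal per-second stepper for the replica. `R` carries the continuous
# internal state (position, orbit phases, current y-speed, sweep direction).
# Returns 30 Hz frames for one second plus the updated internal state. On a
# behavior change the first second glides linearly to the new program's entry
# point so that the trajectory stays continuous.
robot_init <- function(arena, params) {
  list(pos = c(-arena$lateral_length_cm / 2, arena$central_width_cm / 2,
               arena$water_depth_cm / 2),
       phase_x = 0, phase_y = 0,
       speed_y = params$speed_y_cm_s,
       sweep_y = arena$central_width_cm / 2, sweep_dir = 1,
       prev_state = NA_character_)
}

robot_second <- function(state, R, params, arena) {
  fps <- params$frame_rate_hz
  dt <- 1 / fps
  cx <- -arena$lateral_length_cm / 2
  cy <- arena$central_width_cm / 2
  floor_z <- 0.5
  entering <- !identical(state, R$prev_state)
  frames <- matrix(NA_real_, fps, 3)

  if (state == "St") {
    # dive toward the bottom, then freeze
    z <- R$pos[3]
    zs <- pmax(floor_z, z - params$descent_speed_cm_s * dt * seq_len(fps))
    frames[, 1] <- R$pos[1]; frames[, 2] <- R$pos[2]; frames[, 3] <- zs
    R$pos <- frames[fps, ]
  } else if (state == "Sw") {
    # stochastic per-occurrence perturbations of the orbit
    if (stats::runif(1) < params$speed_jitter_prob)
      R$speed_y <- max(0.1, R$speed_y +
                         sample(c(-1, 1), 1) * params$speed_jitter_cm_s)
    z_target <- R$pos[3]
    if (stats::runif(1) < params$vertical_step_prob) {
      dirs <- c(-1, 1)[c(z_target - params$vertical_step_cm >= floor_z,
                         z_target + params$vertical_step_cm <=
                           arena$water_depth_cm - 0.5)]
      if (length(dirs))
        z_target <- z_target +
          dirs[sample.int(length(dirs), 1)] * params$vertical_step_cm
    }
    ax <- params$ellipse_axis_minor_cm / 2
    ay <- params$ellipse_axis_major_cm / 2
    wx <- params$speed_x_cm_s / ax
    wy <- R$speed_y / ay
    tt <- dt * seq_len(fps)
    px <- cx + ax * sin(R$phase_x + wx * tt)
    py <- cy + ay * sin(R$phase_y + wy * tt)
    pz <- R$pos[3] + (z_target - R$pos[3]) * tt
    if (entering) {
      # glide from the current position onto the orbit over this second
      px <- (1 - tt) * R$pos[1] + tt * px
      py <- (1 - tt) * R$pos[2] + tt * py
    }
    frames[, 1] <- px; frames[, 2] <- py; frames[, 3] <- pz
    R$phase_x <- R$phase_x + wx
    R$phase_y <- R$phase_y + wy
    R$pos <- frames[fps, ]
  } else if (state == "A") {
    # thrashing: constant-speed sweep along the wall next to the central tank
    margin <- 2
    lo <- margin; hi <- arena$central_width_cm - margin
    y <- R$sweep_y; dir <- R$sweep_dir
    ys <- numeric(fps)
    for (f in seq_len(fps)) {
      y <- y + dir * params$attack_speed_cm_s * dt
      if (y > hi) { y <- 2 * hi - y; dir <- -dir }
      if (y < lo) { y <- 2 * lo - y; dir <- -dir }
      ys[f] <- y
    }
    px <- rep(-1, fps); pz <- rep(R$pos[3], fps)
    if (entering) {
      tt <- dt * seq_len(fps)
      px <- (1 - tt) * R$pos[1] + tt * px
      ys <- (1 - tt) * R$pos[2] + tt * ys
    }
    frames[, 1] <- px; frames[, 2] <- ys; frames[, 3] <- pz
    R$sweep_y <- y; R$sweep_dir <- dir
    R$pos <- frames[fps, ]
  } else stop("unknown replica state: ", state)

  R$prev_state <- state
  list(frames = frames, R = R)
}

#' Simulate the replica's trajectory for a behavior schedule
#'
#' Renders a 1 Hz behavior-state sequence into a 30 Hz trajectory confined to
#' the lateral tank: stationary states descend to the bottom and freeze,
#' swimming states follow the stochastic elliptical orbit, attacking states
#' sweep back and forth along the wall adjacent to the central tank.
#'
#' @param states Character vector of 1 Hz behavior states.
#' @param params A [robot_kinematics()].
#' @param arena An [arena_geometry()].
#' @return Data frame with columns `t_s`, `x_cm`, `y_cm`, `z_cm` at 30 Hz.
#' @export
simulate_robot_motion <- function(states, params = robot_kinematics(),
                                  arena = arena_geometry()) {
  R <- robot_init(arena, params)
  fps <- params$frame_rate_hz
  out <- matrix(NA_real_, length(states) * fps, 3)
  for (k in seq_along(states)) {
    st <- robot_second(states[k], R, params, arena)
    out[((k - 1) * fps + 1):(k * fps), ] <- st$frames
    R <- st$R
  }
  data.frame(t_s = seq_len(nrow(out)) / fps,
             x_cm = out[, 1], y_cm = out[, 2], z_cm = out[, 3])
}

# --- fish movement ----------------------------------------------------------

fish_init <- function(arena) {
  list(pos = c(arena$central_length_cm / 2, arena$central_width_cm / 2,
               arena$water_depth_cm / 2),
       heading = stats::runif(1, 0, 2 * pi))
}

# One second (fps frames) of the bounded correlated random walk.
# `robot_attacking` and `robot_lower` describe the concurrent replica state;
# coupling is active only when gains are positive and `visible` is TRUE
# (the replica is hidden behind a curtain during habituation).
fish_second <- function(F, params, arena, fps, visible,
                        robot_attacking, robot_lower) {
  dt <- 1 / fps
  L <- arena$central_length_cm; W <- arena$central_width_cm
  D <- arena$water_depth_cm
  z_pref <- if (visible) 0.5 * D else params$habituation_bias * D
  avoid_v <- 0; avoid_h <- 0
  if (visible && robot_attacking) {
    if (params$gain_vertical > 0) {
      z_pref <- if (robot_lower) 0.75 * D else 0.25 * D
      avoid_v <- params$gain_vertical *
        (if (robot_lower) 1 else -1) * params$mean_speed_cm_s * 0.5
    }
    avoid_h <- params$gain_horizontal * params$mean_speed_cm_s
  }
  dh <- stats::rnorm(fps, 0, params$turning_noise_rad)
  sp <- pmax(0, stats::rnorm(fps, params$mean_speed_cm_s, params$speed_sd_cm_s))
  zn <- stats::rnorm(fps, 0, params$vertical_noise_cm_s * sqrt(dt))
  x <- F$pos[1]; y <- F$pos[2]; z <- F$pos[3]; h <- F$heading
  frames <- matrix(NA_real_, fps, 3)
  third <- L / 3
  for (f in seq_len(fps)) {
    h <- h + dh[f]
    dx <- sp[f] * cos(h) * dt
    dy <- sp[f] * sin(h) * dt
    if (avoid_h > 0 && x < third) dx <- dx + avoid_h * dt
    x <- x + dx
    if (x < 0) { x <- -x; h <- pi - h }
    if (x > L) { x <- 2 * L - x; h <- pi - h }
    y <- y + dy
    if (y < 0) { y <- -y; h <- -h }
    if (y > W) { y <- 2 * W - y; h <- -h }
    z <- z + (params$vertical_drift * (z_pref - z) + avoid_v) * dt + zn[f]
    if (z < 0) z <- -z
    if (z > D) z <- 2 * D - z
    frames[f, ] <- c(x, y, z)
  }
  F$pos <- c(x, y, z); F$heading <- h
  list(frames = frames, F = F)
}

#' Simulate the fish as a bounded correlated random walk
#'
#' Stands in for the live zebrafish: a 30 Hz stochastic trajectory inside the
#' central tank with persistent heading, fluctuating speed, mean-reverting
#' vertical dynamics and reflecting walls. When an avoidance gain is positive
#' and the concurrent replica state (after the habituation period) is
#' attacking, the fish drifts vertically toward the half of the water column
#' opposite the replica and/or longitudinally out of the replica-side third.
#'
#' @param params A [fish_params()].
#' @param robot_states Character vector of 1 Hz replica behavior states
#'   (`"none"` entries, as in the control condition, never trigger coupling).
#' @param arena An [arena_geometry()].
#' @param robot_z Optional 1 Hz vector of replica heights, used to decide
#'   which vertical half the replica occupies; replica assumed in the lower
#'   half when omitted.
#' @param habituation_s Seconds at the start of the trial during which the
#'   replica is hidden and coupling is inactive.
#' @param frame_rate_hz Sampling rate of the output trajectory.
#' @return Data frame with columns `t_s`, `x_cm`, `y_cm`, `z_cm`.
#' @export
simulate_fish <- function(params = fish_params(), robot_states,
                          arena = arena_geometry(), robot_z = NULL,
                          habituation_s = 0, frame_rate_hz = 30) {
  fps <- frame_rate_hz
  n_s <- length(robot_states)
  if (is.null(robot_z)) robot_z <- rep(0, n_s)
  F <- fish_init(arena)
  out <- matrix(NA_real_, n_s * fps, 3)
  mid <- arena$water_depth_cm / 2
  for (k in seq_len(n_s)) {
    st <- fish_second(F, params, arena, fps,
                      visible = k > habituation_s,
                      robot_attacking = identical(robot_states[k], "A"),
                      robot_lower = robot_z[k] <= mid)
    out[((k - 1) * fps + 1):(k * fps), ] <- st$frames
    F <- st$F
  }
  data.frame(t_s = seq_len(nrow(out)) / fps,
             x_cm = out[, 1], y_cm = out[, 2], z_cm = out[, 3])
}

# --- full trials ------------------------------------------------------------

#' Simulate one full trial
#'
#' Runs a complete 16-min trial (10 min habituation + 6 min observation by
#' default) in one of the three experimental conditions. In the control
#' condition the replica is absent: the robot trajectory is a constant
#' placeholder at the geometric center of the lateral tank's water volume,
#' the state stream is `"none"`, and the fish runs uncoupled. In open loop
#' the replica follows a pre-generated schedule from the three-state chain,
#' starting stationary. In closed loop each 1 Hz transition is drawn from the
#' six-state joint chain using the fish's current proximity class.
#'
#' @param condition `"control"`, `"open_loop"` or `"closed_loop"`.
#' @param seed Integer seed; the single RNG stream of the trial.
#' @param M Transition matrix for the condition: the three-state open-loop
#'   chain or the six-state closed-loop chain. Defaults to the calibrated
#'   chains; ignored for control.
#' @param kinematics A [robot_kinematics()].
#' @param fish A [fish_params()].
#' @param arena An [arena_geometry()].
#' @param habituation_s,observation_s Trial phase durations, seconds.
#' @return A `trial_record`: list with `condition`, `arena`, `fish_traj`,
#'   `robot_traj` (30 Hz data frames), `robot_states` (1 Hz), phase
#'   durations, `seed`, and the parameter objects.
#' @export
run_trial <- function(condition = c("control", "open_loop", "closed_loop"),
                      seed, M = NULL,
                      kinematics = robot_kinematics(),
                      fish = fish_params(),
                      arena = arena_geometry(),
                      habituation_s = 600, observation_s = 360) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  duration_s <- habituation_s + observation_s
  fps <- kinematics$frame_rate_hz

  if (condition == "control") {
    robot_states <- rep("none", duration_s)
    center <- c(-arena$lateral_length_cm / 2, arena$central_width_cm / 2,
                arena$water_depth_cm / 2)
    n <- duration_s * fps
    robot_traj <- data.frame(t_s = seq_len(n) / fps, x_cm = center[1],
                             y_cm = center[2], z_cm = center[3])
    fish0 <- fish; fish0$gain_vertical <- 0; fish0$gain_horizontal <- 0
    fish_traj <- simulate_fish(fish0, robot_states, arena,
                               habituation_s = habituation_s,
                               frame_rate_hz = fps)
    fish <- fish0
  } else if (condition == "open_loop") {
    if (is.null(M)) M <- open_loop_matrix()
    if (nrow(M) != 3) stop("open loop requires the three-state chain")
    robot_states <- generate_open_loop_schedule(M, duration_s)
    robot_traj <- simulate_robot_motion(robot_states, kinematics, arena)
    robot_z <- robot_traj$z_cm[seq(1, duration_s) * fps]
    fish_traj <- simulate_fish(fish, robot_states, arena, robot_z = robot_z,
                               habituation_s = habituation_s,
                               frame_rate_hz = fps)
  } else {
    if (is.null(M)) M <- closed_loop_matrix()
    if (nrow(M) != 6) stop("closed loop requires the six-state joint chain")
    R <- robot_init(arena, kinematics)
    F <- fish_init(arena)
    robot_states <- character(duration_s)
    behavior <- "St"
    robot_mat <- matrix(NA_real_, duration_s * fps, 3)
    fish_mat <- matrix(NA_real_, duration_s * fps, 3)
    mid <- arena$water_depth_cm / 2
    for (k in seq_len(duration_s)) {
      if (k > 1) {
        prox <- classify_proximity(F$pos, R$pos[3], arena)
        behavior <- step_closed_loop(M, behavior, prox)
      }
      robot_states[k] <- behavior
      rs <- robot_second(behavior, R, kinematics, arena)
      fs <- fish_second(F, fish, arena, fps,
                        visible = k > habituation_s,
                        robot_attacking = identical(behavior, "A"),
                        robot_lower = R$pos[3] <= mid)
      rows <- ((k - 1) * fps + 1):(k * fps)
      robot_mat[rows, ] <- rs$frames
      fish_mat[rows, ] <- fs$frames
      R <- rs$R; F <- fs$F
    }
    t_s <- seq_len(duration_s * fps) / fps
    robot_traj <- data.frame(t_s = t_s, x_cm = robot_mat[, 1],
                             y_cm = robot_mat[, 2], z_cm = robot_mat[, 3])
    fish_traj <- data.frame(t_s = t_s, x_cm = fish_mat[, 1],
                            y_cm = fish_mat[, 2], z_cm = fish_mat[, 3])
  }

  structure(list(condition = condition, arena = arena,
                 fish_traj = fish_traj, robot_traj = robot_traj,
                 robot_states = robot_states,
                 habituation_s = habituation_s,
                 observation_s = observation_s,
                 seed = as.integer(seed),
                 kinematics = kinematics, fish = fish),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial (%s), %d s (%d habituation + %d observation), seed %d\n",
              x$condition, x$habituation_s + x$observation_s,
              x$habituation_s, x$observation_s, x$seed))
  tab <- table(x$robot_states)
  cat("Replica states: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a trial record as plain-text files
#'
#' A trial is serialized as a directory holding `fish.csv` and `robot.csv`
#' (columns `t_s`, `x_cm`, `y_cm`, `z_cm`), `states.csv` (`t_s`, `state`) and
#' `meta.json`. Positions are written with 17 significant digits so that a
#' round trip is bit-identical.
#'
#' @param trial A `trial_record`.
#' @param dir Directory path (created if needed).
#' @return `write_trial` returns `dir` invisibly; `read_trial` returns the
#'   reconstructed `trial_record`.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    df[] <- lapply(df, function(v)
      if (is.numeric(v)) formatC(v, digits = 17, format = "g") else v)
    df
  }
  utils::write.csv(fmt(trial$fish_traj), file.path(dir, "fish.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(trial$robot_traj), file.path(dir, "robot.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(t_s = seq_along(trial$robot_states),
                              state = trial$robot_states),
                   file.path(dir, "states.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(condition = trial$condition,
               arena = unclass(trial$arena),
               habituation_s = trial$habituation_s,
               observation_s = trial$observation_s,
               seed = trial$seed,
               kinematics = unclass(trial$kinematics),
               fish = unclass(trial$fish))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  arena <- do.call(arena_geometry, meta$arena)
  kin <- do.call(robot_kinematics, meta$kinematics)
  fish <- do.call(fish_params, meta$fish)
  structure(list(condition = meta$condition, arena = arena,
                 fish_traj = utils::read.csv(file.path(dir, "fish.csv")),
                 robot_traj = utils::read.csv(file.path(dir, "robot.csv")),
                 robot_states = utils::read.csv(
                   file.path(dir, "states.csv"),
                   colClasses = c("integer", "character"))$state,
                 habituation_s = meta$habituation_s,
                 observation_s = meta$observation_s,
                 seed = meta$seed, kinematics = kin, fish = fish),
            class = "trial_record")
}
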
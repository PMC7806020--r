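test_that("moving average keeps length, constants, and affine interiors", {
  expect_equal(moving_average(rep(4, 50), 18), rep(4, 50))
  ramp <- seq(0, 10, length.out = 100)
  # an odd centered window preserves affine interiors exactly
  expect_equal(moving_average(ramp, 17)[20:80], ramp[20:80])
  # the even 18-frame window spans [t-9, t+8], shifting a ramp by half the
  # per-sample increment in the interior
  sm <- moving_average(ramp, 18)
  expect_length(sm, 100)
  expect_equal(sm[20:80], ramp[20:80] - 0.5 * (ramp[2] - ramp[1]))
  # alternating +/-1 with an even window averages to zero in the interior
  alt <- rep(c(1, -1), 30)
  expect_equal(moving_average(alt, 18)[10:50], rep(0, 41))
  expect_error(moving_average(1:5, 18), "window larger")
})

test_that("speed and acceleration recover closed-form kinematics", {
  # uniform motion: 1 cm per frame along x at 30 Hz
  tr <- make_traj(x = cumsum(rep(1, 300)), y = 0, z = 0)
  sp <- speed_series(tr)
  expect_equal(sp[30:260], rep(30, 231), tolerance = 1e-9)
  expect_equal(accel_series(tr)[30:250], rep(0, 221), tolerance = 1e-6)
  # stationary fish
  still <- make_traj(5, 5, 5, n = 100)
  expect_equal(speed_series(still), rep(0, 99))
  expect_equal(accel_series(still), rep(0, 98))
  # circular orbit, smoothing disabled: |v| = r*Omega, |a| = r*Omega^2
  r <- 4; Om <- 1
  t <- seq(0, 20, by = 1 / 30)
  circ <- data.frame(t_s = t, x_cm = r * cos(Om * t),
                     y_cm = r * sin(Om * t), z_cm = 0)
  expect_equal(mean(speed_series(circ, smooth_window = 0)), r * Om,
               tolerance = 1e-3)
  expect_equal(mean(accel_series(circ, smooth_window = 0)), r * Om^2,
               tolerance = 1e-3)
})

test_that("turn rate implements the angular formula with clamping", {
  # straight path: parallel velocities, zero turn rate
  tr <- make_traj(x = cumsum(rep(0.5, 200)), y = 0, z = 0)
  expect_equal(turn_rate_series(tr, smooth_window = 0), rep(0, 198))
  # a single 90-degree heading change at 30 Hz
  path <- rbind(cbind(seq_len(50), 0), cbind(50, seq_len(50)))
  tr90 <- data.frame(t_s = seq_len(100) / 30, x_cm = path[, 1],
                     y_cm = path[, 2], z_cm = 0)
  w <- turn_rate_series(tr90, smooth_window = 0)
  expect_equal(max(w), (pi / 2) * 30, tolerance = 1e-9)
  # full velocity reversal: arccos clamped at -1
  xrev <- c(seq_len(50), rev(seq_len(50) - 1))
  trrev <- data.frame(t_s = seq_along(xrev) / 30, x_cm = xrev, y_cm = 0,
                      z_cm = 0)
  expect_equal(max(turn_rate_series(trrev, smooth_window = 0)), pi * 30,
               tolerance = 1e-9)
  # zero-velocity frames yield no turn-rate sample
  trstop <- make_traj(x = c(1:10, rep(10, 10), 11:20), y = 0, z = 0)
  expect_true(anyNA(turn_rate_series(trstop, smooth_window = 0)))
})

test_that("kinematics are invariant under rigid motions of the path", {
  set.seed(8)
  tr <- make_traj(x = cumsum(rnorm(200, 0.3)), y = cumsum(rnorm(200, 0.1)),
                  z = cumsum(rnorm(200, 0, 0.1)))
  shift <- tr
  shift[, c("x_cm", "y_cm", "z_cm")] <-
    shift[, c("x_cm", "y_cm", "z_cm")] + rep(c(3, -2, 1), each = 200)
  expect_equal(speed_series(shift), speed_series(tr))
  expect_equal(accel_series(shift), accel_series(tr))
  expect_equal(turn_rate_series(shift), turn_rate_series(tr))
  th <- 0.7
  rot <- tr
  rot$x_cm <- cos(th) * tr$x_cm - sin(th) * tr$y_cm
  rot$y_cm <- sin(th) * tr$x_cm + cos(th) * tr$y_cm
  expect_equal(speed_series(rot), speed_series(tr))
})

test_that("avoidance metrics follow their definitions", {
  n <- 30 * 60
  # fish and robot mirrored across the vertical midline at all times
  fish <- make_traj(10, 15, c(3, 12), n = n)
  robot <- make_traj(-8, 15, c(12, 3), n = n)
  tr <- make_trial(fish, robot)
  expect_equal(avoidance_metrics(tr)$pct_time_opposite_half, 100)
  # always the same half
  tr2 <- make_trial(make_traj(10, 15, 3, n = n), make_traj(-8, 15, 6, n = n))
  expect_equal(avoidance_metrics(tr2)$pct_time_opposite_half, 0)
  # fixed geometry: plain Euclidean distance
  tr3 <- make_trial(make_traj(21, 15, 7.5, n = n),
                    make_traj(-8, 15, 7.5, n = n))
  expect_equal(avoidance_metrics(tr3)$avg_distance_cm, 29)
  # control condition has no replica: opposite-half measure undefined
  trc <- make_trial(fish, robot, condition = "control")
  expect_true(is.na(avoidance_metrics(trc)$pct_time_opposite_half))
})

test_that("geotaxis metrics count bottom occupancy and entries", {
  n <- 30 * 360
  low <- make_trial(make_traj(21, 15, 2, n = n))
  g <- geotaxis_metrics(low)
  expect_equal(g$avg_height_cm, 2)
  expect_equal(g$pct_time_bottom, 100)
  expect_equal(g$n_entries_bottom, 0L)
  high <- make_trial(make_traj(21, 15, 14, n = n))
  expect_equal(geotaxis_metrics(high)$pct_time_bottom, 0)
  # sinusoidal depth crossing into the bottom section once per minute
  t <- seq_len(n) / 30
  sin_tr <- make_trial(data.frame(t_s = t, x_cm = 21, y_cm = 15,
                                  z_cm = 7.5 + 5 * sin(2 * pi * t / 60)))
  expect_equal(geotaxis_metrics(sin_tr)$n_entries_bottom, 6L)
  # entry count equals the brute-force count of outside-to-inside crossings
  set.seed(13)
  z <- pmin(15, pmax(0, 7.5 + cumsum(rnorm(n, 0, 0.2))))
  rw <- make_trial(data.frame(t_s = t, x_cm = 21, y_cm = 15, z_cm = z))
  zs <- moving_average(z, 18)
  s <- sign(zs - 5)
  brute <- sum(s[-1] < 0 & s[-length(s)] >= 0)
  expect_equal(geotaxis_metrics(rw)$n_entries_bottom, brute)
})

test_that("time binning computes time-weighted means per 2-min bin", {
  expect_equal(as.numeric(bin_by_time(rep(7, 360))), rep(7, 3))
  tt <- seq(1 / 30, 360, by = 1 / 30)
  expect_equal(as.numeric(bin_by_time(tt, tt)), c(60, 180, 300),
               tolerance = 1e-3)
  step <- ifelse(tt <= 120, 1, 5)
  expect_equal(as.numeric(bin_by_time(step, tt)), c(1, 5, 5))
  expect_equal(names(bin_by_time(rep(1, 360))),
               c("0-2 min", "2-4 min", "4-6 min"))
})

test_that("the per-trial metric table is tidy and internally consistent", {
  tr <- run_trial("open_loop", seed = 2, habituation_s = 60,
                  observation_s = 360)
  m <- trial_metrics(tr, trial_id = "ol_1")
  expect_equal(nrow(m), 3)
  expect_equal(m$time_bin, c("0-2 min", "2-4 min", "4-6 min"))
  pct <- unlist(m[, grep("^pct_", names(m))])
  expect_true(all(pct >= 0 & pct <= 100, na.rm = TRUE))
  expect_true(all(m$n_entries_bottom >= 0))
  # occupancy measures agree with the whole-window helpers on average
  occ <- robot_occupancy(tr)
  expect_equal(mean(m$pct_robot_attacking), occ$pct_robot_attacking)
  expect_equal(mean(m$pct_robot_lower_half), occ$pct_robot_lower_half)
  av <- avoidance_metrics(tr)
  expect_equal(mean(m$avg_distance_to_replica_cm), av$avg_distance_cm)
})

test_that("replica occupancy handles degenerate schedules", {
  n <- 30 * 360
  t <- seq_len(n) / 30
  states <- rep(c("A", "Sw"), each = 180)
  tr <- make_trial(make_traj(21, 15, 7.5, n = n),
                   make_traj(-8, 15, 2, n = n),
                   robot_states = states)
  occ <- robot_occupancy(tr)
  expect_equal(occ$pct_robot_lower_half, 100)
  expect_equal(occ$pct_robot_attacking, 50)
  trc <- make_trial(make_traj(21, 15, 7.5, n = n), condition = "control")
  expect_true(is.na(robot_occupancy(trc)$pct_robot_attacking))
})
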
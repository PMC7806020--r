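test_that("open-loop schedules start stationary and converge to pi_OL", {
  M <- open_loop_matrix()
  set.seed(3)
  sched <- generate_open_loop_schedule(M, 1200)
  expect_length(sched, 1200)
  expect_equal(sched[1], "St")
  expect_true(all(sched %in% behavior_states()))
  # absorbing start under an identity chain
  Mid <- transition_matrix(diag(3), behavior_states())
  expect_true(all(generate_open_loop_schedule(Mid, 100) == "St"))
  # long-run occupancy approaches the stationary distribution; the chain is
  # strongly autocorrelated (diagonal ~0.95), so a long run is needed for
  # the occupancy standard error to sit well below the bound
  set.seed(5)
  long <- generate_open_loop_schedule(M, 5e5)
  freq <- table(factor(long, levels = behavior_states())) / 5e5
  pi_OL <- stationary_distribution(M)
  expect_lt(max(abs(as.numeric(freq) - as.numeric(pi_OL))), 0.01)
})

test_that("closed-loop stepping samples the joint row's behavior marginal", {
  M <- closed_loop_matrix()
  set.seed(9)
  draws <- replicate(2e4, step_closed_loop(M, "Sw", "C"))
  freq <- table(factor(draws, levels = behavior_states())) / 2e4
  row <- as.numeric(M["Sw-C", ])
  expected <- c(row[1] + row[2], row[3] + row[4], row[5] + row[6])
  expect_lt(max(abs(as.numeric(freq) - expected)), 0.01)
  expect_equal(expected[3], 0.034)  # attack probability from Sw-C
})

test_that("replica movement honors the per-state motion programs", {
  arena <- arena_geometry()
  # stationary: monotone descent to the bottom, then frozen
  set.seed(1)
  tr <- simulate_robot_motion(rep("St", 20), robot_kinematics(), arena)
  expect_true(all(diff(tr$z_cm) <= 1e-12))
  expect_equal(tail(tr$z_cm, 1), 0.5)
  expect_equal(tail(diff(tr$z_cm), 30), rep(0, 30))
  # swimming without jitter: bounded elliptical orbit about the tank center
  kin0 <- robot_kinematics(speed_jitter_prob = 0, vertical_step_prob = 0)
  set.seed(2)
  orb <- simulate_robot_motion(rep("Sw", 120), kin0, arena)
  orb <- orb[orb$t_s > 2, ]  # skip the entry glide
  expect_lt(max(abs(orb$x_cm + arena$lateral_length_cm / 2)), 2.35 / 2 + 1e-9)
  expect_lt(max(abs(orb$y_cm - arena$central_width_cm / 2)), 10 / 2 + 1e-9)
  expect_equal(sd(orb$z_cm), 0)
  # vertical 1 cm steps occur in about 20% of swim seconds
  set.seed(3)
  long <- simulate_robot_motion(rep("Sw", 3000), robot_kinematics(), arena)
  z_sec <- long$z_cm[seq(30, nrow(long), 30)]
  moved <- abs(diff(z_sec)) > 0.5
  expect_equal(mean(moved), 0.2, tolerance = 0.04)
  # attacking: hugs the wall adjacent to the central tank
  set.seed(4)
  atk <- simulate_robot_motion(rep("A", 60), robot_kinematics(), arena)
  atk <- atk[atk$t_s > 2, ]
  expect_true(all(atk$x_cm == -1))
  expect_gt(diff(range(atk$y_cm)), 10)
})

test_that("fish walk stays in the tank and decouples at zero gain", {
  arena <- arena_geometry()
  states <- rep(c("Sw", "A"), 30)
  p0 <- fish_params(gain_vertical = 0, gain_horizontal = 0)
  set.seed(21)
  f1 <- simulate_fish(p0, states, arena)
  expect_true(all(f1$x_cm >= 0 & f1$x_cm <= 42))
  expect_true(all(f1$y_cm >= 0 & f1$y_cm <= 30))
  expect_true(all(f1$z_cm >= 0 & f1$z_cm <= 15))
  # zero gain: trajectory identical whether the robot attacks or not
  set.seed(21)
  f2 <- simulate_fish(p0, rep("Sw", 60), arena)
  expect_identical(f1, f2)
  # positive gain changes the law
  set.seed(21)
  f3 <- simulate_fish(fish_params(gain_vertical = 1), states, arena)
  expect_false(identical(f1$z_cm, f3$z_cm))
})

test_that("vertical avoidance gain pushes the fish opposite the replica", {
  arena <- arena_geometry()
  states <- rep("A", 60)  # replica attacking in the lower half throughout
  frac_upper <- function(g, seed) {
    set.seed(seed)
    f <- simulate_fish(fish_params(gain_vertical = g), states, arena,
                       robot_z = rep(1, 60))
    mean(f$z_cm > arena$water_depth_cm / 2)
  }
  up0 <- mean(vapply(1:25, function(s) frac_upper(0, s), numeric(1)))
  up1 <- mean(vapply(1:25, function(s) frac_upper(1, s), numeric(1)))
  expect_gt(up1, up0 + 0.1)
})

test_that("trials have the published structure and are reproducible", {
  t1 <- run_trial("closed_loop", seed = 123)
  expect_length(t1$robot_states, 960)
  expect_equal(nrow(t1$fish_traj), 960 * 30)
  expect_equal(t1$observation_s, 360)
  t2 <- run_trial("closed_loop", seed = 123)
  expect_identical(t1, t2)
  t3 <- run_trial("closed_loop", seed = 124)
  expect_false(identical(t1$fish_traj, t3$fish_traj))
  # control: placeholder robot, uncoupled fish
  tc <- run_trial("control", seed = 5, habituation_s = 30, observation_s = 120)
  expect_true(all(tc$robot_states == "none"))
  expect_equal(unique(tc$robot_traj$x_cm), -8)
  expect_equal(tc$fish$gain_vertical, 0)
  # condition/matrix mismatch
  expect_error(run_trial("open_loop", seed = 1, M = closed_loop_matrix()),
               "three-state")
  expect_error(run_trial("closed_loop", seed = 1, M = open_loop_matrix()),
               "six-state")
})

test_that("realized closed-loop transitions follow the commanded chain", {
  # With a long trial, re-calibrating a chain on the realized
  # (behavior, proximity) sequence must recover the behavior-destination
  # marginals of the commanded joint chain on visited rows. (The proximity
  # component of the next state is fish-driven, so full-matrix recovery is
  # not expected.)
  M <- closed_loop_matrix()
  tr <- run_trial("closed_loop", seed = 31, habituation_s = 0,
                  observation_s = 5000)
  fps <- 30
  n <- length(tr$robot_states)
  # proximity as measured at each decision instant (end of previous second)
  prox <- vapply(2:n, function(k) {
    f <- as.numeric(tr$fish_traj[(k - 1) * fps, c("x_cm", "y_cm", "z_cm")])
    classify_proximity(f, tr$robot_traj$z_cm[(k - 1) * fps], tr$arena)
  }, character(1))
  joint <- paste(tr$robot_states[-n], prox, sep = "-")
  nxt <- tr$robot_states[-1]
  for (js in unique(joint)) {
    sel <- joint == js
    if (sum(sel) < 300) next
    emp <- table(factor(nxt[sel], levels = behavior_states())) / sum(sel)
    row <- as.numeric(M[js, ])
    expected <- c(row[1] + row[2], row[3] + row[4], row[5] + row[6])
    expect_lt(max(abs(as.numeric(emp) - expected)), 0.05)
  }
})

test_that("trial records round-trip through the plain-text serialization", {
  tr <- run_trial("open_loop", seed = 17, habituation_s = 30,
                  observation_s = 120)
  dir <- withr::local_tempdir()
  write_trial(tr, dir)
  expect_setequal(list.files(dir),
                  c("fish.csv", "robot.csv", "states.csv", "meta.json"))
  back <- read_trial(dir)
  expect_identical(back$robot_states, tr$robot_states)
  expect_equal(back$fish_traj, tr$fish_traj, tolerance = 0)
  # metrics computed before and after the round trip are bit-identical
  expect_identical(trial_metrics(back, trial_id = "x"),
                   trial_metrics(tr, trial_id = "x"))
})
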
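# Shared fixtures: closed-form trajectories and minimal trial records.

make_traj <- function(x, y, z, n = max(length(x), length(y), length(z)),
                      fps = 30) {
  data.frame(t_s = seq_len(n) / fps,
             x_cm = rep_len(x, n), y_cm = rep_len(y, n), z_cm = rep_len(z, n))
}

# Minimal trial record wrapping prescribed trajectories (no habituation).
make_trial <- function(fish, robot = NULL, condition = "closed_loop",
                       robot_states = NULL, arena = arena_geometry(),
                       fps = 30) {
  obs_s <- nrow(fish) / fps
  if (is.null(robot))
    robot <- make_traj(-8, 15, 7.5, n = nrow(fish), fps = fps)
  if (is.null(robot_states))
    robot_states <- rep(if (condition == "control") "none" else "Sw", obs_s)
  structure(list(condition = condition, arena = arena,
                 fish_traj = fish, robot_traj = robot,
                 robot_states = robot_states,
                 habituation_s = 0, observation_s = obs_s,
                 seed = 0L, kinematics = robot_kinematics(),
                 fish = fish_params()),
            class = "trial_record")
}

# Independent brute-force oracle for the max-attack-window scan.
brute_force_window <- function(fr, w) {
  totals <- vapply(seq_len(length(fr) - w + 1),
                   function(s) sum(fr[s:(s + w - 1)]), numeric(1))
  list(start = which.max(totals), total = max(totals))
}

# Independent brute-force oracle for the plug-in transfer entropy: explicit
# triple loop over all (F_{t+1}, F_t, R_t) values using empirical frequencies.
brute_force_te <- function(source, target) {
  n <- length(source)
  f1 <- target[-1]; f0 <- target[-n]; r0 <- source[-n]
  N <- n - 1
  te <- 0
  for (a in unique(f1)) for (b in unique(f0)) for (c in unique(r0)) {
    n_abc <- sum(f1 == a & f0 == b & r0 == c)
    if (n_abc == 0) next
    n_bc <- sum(f0 == b & r0 == c)
    n_ab <- sum(f1 == a & f0 == b)
    n_b <- sum(f0 == b)
    te <- te + (n_abc / N) * log2((n_abc / n_bc) / (n_ab / n_b))
  }
  te
}

# Sample a state sequence of length n from a transition matrix.
sample_chain <- function(M, n, start = rownames(M)[1]) {
  states <- rownames(M)
  out <- character(n)
  out[1] <- start
  for (t in 2:n) out[t] <- sample_next_state(M, out[t - 1])
  out
}
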
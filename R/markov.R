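#' Locate the window with the largest total attack fraction
#'
#' Given a per-second series of attack fractions (the fraction of scored
#' videos reporting an attack at each second), finds the contiguous window of
#' `window_s` samples whose summed fraction is largest. The chain is then
#' calibrated on that segment. Ties are broken in favor of the earliest start.
#'
#' @param attack_fractions Numeric vector of per-second fractions in `[0, 1]`.
#' @param window_s Integer window length in samples (seconds); default 60.
#' @return A list with `start` (1-based start index), and `total`
#'   (the summed fraction inside the window).
#' @export
select_max_attack_window <- function(attack_fractions, window_s = 60) {
  n <- length(attack_fractions)
  window_s <- as.integer(window_s)
  if (window_s < 1)
    stop("window_s must be >= 1")
  if (n < window_s)
    stop(sprintf("series too short: %d samples < window of %d", n, window_s))
  if (any(!is.finite(attack_fractions)) ||
      any(attack_fractions < 0) || any(attack_fractions > 1))
    stop("attack fractions must be finite and in [0, 1]")
  csum <- c(0, cumsum(attack_fractions))
  totals <- csum[(window_s + 1):(n + 1)] - csum[1:(n - window_s + 1)]
  start <- which.max(totals)  # which.max returns the earliest maximum
  list(start = start, total = totals[start])
}

#' Calibrate a transition matrix from a scored state sequence
#'
#' Maximum-likelihood estimate of the transition matrix: entry (i, j) is the
#' number of observed i to j transitions divided by the number of departures
#' from i. States never departed from (including states never visited) get an
#' identity row, keeping the matrix stochastic; the labels of such rows are
#' recorded in the `meta` attribute under `absorbing_rows`.
#'
#' @param seq Character (or factor) vector of state labels sampled at a
#'   uniform rate, length at least 2.
#' @param states Character vector fixing the state order of the matrix;
#'   defaults to [joint_states()] when the sequence uses joint labels,
#'   otherwise the sorted unique labels of `seq`.
#' @return A [transition_matrix()].
#' @export
build_transition_matrix <- function(seq, states = NULL) {
  seq <- as.character(seq)
  if (length(seq) < 2)
    stop("need at least 2 observations to count transitions")
  if (is.null(states)) {
    states <- if (all(seq %in% joint_states())) joint_states()
              else if (all(seq %in% behavior_states())) behavior_states()
              else sort(unique(seq))
  }
  if (!all(seq %in% states))
    stop("sequence contains labels outside the supplied state space")
  k <- length(states)
  from <- factor(seq[-length(seq)], levels = states)
  to <- factor(seq[-1], levels = states)
  counts <- table(from, to)
  P <- matrix(as.numeric(counts), k, k)
  departures <- rowSums(P)
  absorbing <- departures == 0
  P[absorbing, ] <- diag(k)[absorbing, , drop = FALSE]
  P <- P / pmax(departures, 1)
  P[absorbing, ] <- diag(k)[absorbing, , drop = FALSE]
  transition_matrix(P, states,
                    meta = list(n_transitions = length(seq) - 1,
                                absorbing_rows = states[absorbing]))
}

#' Stationary distribution of an ergodic chain
#'
#' The long-run occupancy vector pi, the left eigenvector of the transition
#' matrix with unit eigenvalue. Solved as the linear system pi (P - I) = 0
#' with the normalization sum(pi) = 1, which yields a real, nonnegative
#' solution directly; uniqueness (irreducibility of the chain up to
#' transient states) is checked via the multiplicity of the unit eigenvalue.
#'
#' @param M A [transition_matrix()].
#' @return Named numeric vector pi with `sum(pi) == 1` and `pi %*% M == pi`.
#' @export
stationary_distribution <- function(M) {
  if (!inherits(M, "transition_matrix"))
    M <- transition_matrix(M)
  P <- unclass(M)
  k <- nrow(P)
  ev <- eigen(t(P), only.values = TRUE)$values
  if (sum(abs(ev - 1) < 1e-8) != 1)
    stop("stationary distribution is not unique: ",
         "the chain is reducible or periodic")
  A <- rbind(t(P) - diag(k), rep(1, k))
  pi <- qr.solve(A, c(rep(0, k), 1))
  pi[pi < 0 & pi > -1e-12] <- 0
  if (any(pi < 0))
    stop("no nonnegative stationary solution found")
  pi <- pi / sum(pi)
  names(pi) <- rownames(P)
  pi
}

#' Conditional behavior distribution given fish proximity
#'
#' From a stationary distribution over the six joint states, the distribution
#' of replica behavior conditional on the fish being close or far:
#' e.g. P(St | C) = pi(St-C) / (pi(St-C) + pi(Sw-C) + pi(A-C)).
#'
#' @param pi Named numeric stationary vector over [joint_states()].
#' @return List with components `close` and `far`, each a named probability
#'   vector over (St, Sw, A).
#' @export
behavior_given_proximity <- function(pi) {
  js <- joint_states()
  if (length(pi) != 6)
    stop("pi must be defined over the six joint states")
  if (!is.null(names(pi))) {
    if (!setequal(names(pi), js))
      stop("pi names must be the six joint states")
    pi <- pi[js]
  } else names(pi) <- js
  out <- lapply(proximity_states(), function(p) {
    mass <- pi[paste(behavior_states(), p, sep = "-")]
    tot <- sum(mass)
    if (tot <= 0)
      stop("zero stationary mass for proximity state ", p)
    stats::setNames(as.numeric(mass / tot), behavior_states())
  })
  names(out) <- c("close", "far")
  out
}

#' Marginalize the closed-loop chain to the open-loop behavior chain
#'
#' Collapses the six-state joint chain over fish proximity, weighting each
#' joint row by its stationary probability:
#' M_OL(b, b') = sum_p [ sum_p' M_CL((b,p), (b',p')) ] pi_CL(b,p) / pi_OL(b),
#' where pi_OL(b) = sum_p pi_CL(b,p). This is the transition matrix of the
#' behavior marginal of the stationary joint process.
#'
#' @param M_CL Six-state joint [transition_matrix()].
#' @param pi_CL Stationary distribution of `M_CL`; computed when omitted.
#' @return Three-state [transition_matrix()] over (St, Sw, A).
#' @export
marginalize_to_open_loop <- function(M_CL, pi_CL = NULL) {
  if (nrow(M_CL) != 6)
    stop("M_CL must be the six-state joint chain")
  if (is.null(pi_CL))
    pi_CL <- stationary_distribution(M_CL)
  P <- unclass(M_CL)
  if (max(abs(pi_CL %*% P - pi_CL)) > 1e-6)
    stop("pi_CL is not stationary for M_CL")
  b <- behavior_states()
  pi_OL <- vapply(seq_along(b),
                  function(i) sum(pi_CL[(2 * i - 1):(2 * i)]), numeric(1))
  if (any(pi_OL <= 0))
    stop("zero open-loop stationary mass for behavior ",
         paste(b[pi_OL <= 0], collapse = ", "))
  M_OL <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    rows <- (2 * i - 1):(2 * i)
    cols <- (2 * j - 1):(2 * j)
    M_OL[i, j] <- sum(rowSums(P[rows, cols, drop = FALSE]) *
                        pi_CL[rows]) / pi_OL[i]
  }
  transition_matrix(M_OL, b, meta = list(pi_OL = stats::setNames(pi_OL, b)))
}

#' Sample the next state of a chain
#'
#' @param M A [transition_matrix()].
#' @param current Current state label.
#' @return The next state label, drawn from the row of `current` using the
#'   session RNG (seed with [set.seed()] for reproducibility).
#' @export
sample_next_state <- function(M, current) {
  states <- rownames(M)
  i <- match(current, states)
  if (is.na(i))
    stop("unknown state: ", current)
  states[sample.int(length(states), 1L, prob = unclass(M)[i, ])]
}

#' Classify fish proximity to the replica
#'
#' The fish counts as close (`"C"`) when it swims in the longitudinal third of
#' the central tank adjacent to the replica's lateral tank AND occupies the
#' same vertical half of the water column as the replica; otherwise far
#' (`"F"`). The tank length is split into three half-open thirds from the
#' replica-side wall (x = 0); vertical halves are half-open at the midline,
#' with the midline assigned to the lower half.
#'
#' @param fish_pos Numeric length-3 position (x, y, z) of the fish, cm.
#' @param robot_z Vertical position of the replica, cm.
#' @param arena An [arena_geometry()].
#' @return `"C"` or `"F"`.
#' @export
classify_proximity <- function(fish_pos, robot_z, arena = arena_geometry()) {
  x <- fish_pos[1]; z <- fish_pos[3]
  if (x < 0 || x > arena$central_length_cm ||
      z < 0 || z > arena$water_depth_cm)
    stop("fish position outside arena bounds")
  near <- x < arena$central_length_cm / 3
  mid <- arena$water_depth_cm / 2
  same_half <- (z <= mid) == (robot_z <= mid)
  if (near && same_half) "C" else "F"
}
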
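#' State spaces of the predator-replica behavior policy
#'
#' The replica's ethogram has three behavior states: stationary (`"St"`),
#' swimming (`"Sw"`), and attacking (`"A"`). In closed-loop control the chain
#' runs on the joint space of behavior crossed with the fish's proximity to
#' the replica, close (`"C"`) or far (`"F"`), giving six joint states indexed
#' in the fixed order St-C, St-F, Sw-C, Sw-F, A-C, A-F. All matrices and
#' stationary vectors in the package use these orderings.
#'
#' @return Character vector of state labels in canonical order.
#' @export
behavior_states <- function() c("St", "Sw", "A")

#' @rdname behavior_states
#' @export
proximity_states <- function() c("C", "F")

#' @rdname behavior_states
#' @export
joint_states <- function() {
  as.vector(t(outer(behavior_states(), proximity_states(), paste, sep = "-")))
}

#' Construct a row-stochastic transition matrix
#'
#' A `transition_matrix` is a square matrix of transition probabilities over a
#' named finite state space, row = current state, column = next state. Every
#' row must sum to one (tolerance 1e-9) and all entries must lie in `[0, 1]`.
#'
#' @param P Numeric square matrix of transition probabilities.
#' @param states Character vector of state labels, one per row; defaults to
#'   existing dimnames of `P`.
#' @param meta Optional list of metadata (e.g. calibration provenance),
#'   attached as the `"meta"` attribute.
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(P, states = rownames(P), meta = list()) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P))
    stop("transition matrix must be square")
  if (is.null(states))
    stop("state labels are required (supply `states` or dimnames)")
  if (length(states) != nrow(P))
    stop("number of state labels must match matrix dimension")
  if (any(!is.finite(P)) || any(P < -1e-12) || any(P > 1 + 1e-12))
    stop("transition probabilities must lie in [0, 1]")
  bad <- abs(rowSums(P) - 1) > 1e-9
  if (any(bad))
    stop("rows must sum to 1: offending state(s) ",
         paste(states[bad], collapse = ", "))
  dimnames(P) <- list(states, states)
  structure(P, class = c("transition_matrix", "matrix"), meta = meta)
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Transition matrix over %d states: %s\n",
              nrow(x), paste(rownames(x), collapse = ", ")))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Calibrated closed-loop and open-loop transition matrices
#'
#' `closed_loop_matrix()` returns the six-state joint transition matrix of the
#' replica's closed-loop policy, calibrated from per-second scoring of live
#' predator-prey interaction videos over the one-minute segment with the
#' largest total fraction of attacks. `open_loop_matrix()` returns the
#' three-state behavior chain obtained by marginalizing the closed-loop chain
#' over fish proximity (see [marginalize_to_open_loop()]); the stored values
#' are the published three-decimal entries, re-normalized by row so that the
#' object satisfies the row-stochastic contract exactly.
#'
#' @return A [transition_matrix()].
#' @export
closed_loop_matrix <- function() {
  P <- matrix(c(
    0.806, 0.194, 0.000, 0.000, 0.000, 0.000,
    0.075, 0.891, 0.007, 0.027, 0.000, 0.000,
    0.011, 0.023, 0.794, 0.138, 0.034, 0.000,
    0.000, 0.016, 0.060, 0.891, 0.000, 0.033,
    0.000, 0.000, 0.042, 0.000, 0.750, 0.208,
    0.000, 0.000, 0.043, 0.043, 0.203, 0.711),
    nrow = 6, byrow = TRUE)
  transition_matrix(P, joint_states(),
                    meta = list(source = "calibrated closed-loop policy"))
}

#' @rdname closed_loop_matrix
#' @export
open_loop_matrix <- function() {
  P <- matrix(c(
    0.976, 0.024, 0.000,
    0.022, 0.945, 0.033,
    0.000, 0.064, 0.936),
    nrow = 3, byrow = TRUE)
  P <- P / rowSums(P)
  transition_matrix(P, behavior_states(),
                    meta = list(source = "marginalized open-loop policy"))
}
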
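#' Down-sample a 30 Hz series to 1 Hz
#'
#' Keeps every `factor`-th sample, starting from the first.
#'
#' @param x Numeric or character vector sampled at `factor` Hz.
#' @param factor Integer decimation factor (input rate / 1 Hz).
#' @return Vector of every `factor`-th element of `x`.
#' @export
downsample <- function(x, factor = 30) {
  factor <- as.integer(factor)
  if (factor < 1) stop("decimation factor must be a positive integer")
  x[seq(1, length(x), by = factor)]
}

#' Symbolize a position series by 1-body-length binning
#'
#' Bins positions at a resolution of one body length (3 cm) in half-open
#' intervals from 0: the tank length (42 cm) yields 14 bins, the water depth
#' (15 cm) yields 5 bins. A value exactly at the axis upper boundary falls in
#' the last bin. Symbols are integers `0 .. n_bins - 1`.
#'
#' @param values_cm Numeric positions along the chosen axis, cm.
#' @param axis `"length"` or `"depth"`.
#' @param arena An [arena_geometry()].
#' @param bin_cm Bin resolution, cm (1 body length).
#' @return Integer vector with attributes `alphabet_size` and `axis`.
#' @export
bin_position <- function(values_cm, axis = c("length", "depth"),
                         arena = arena_geometry(), bin_cm = 3) {
  axis <- match.arg(axis)
  extent <- switch(axis, length = arena$central_length_cm,
                   depth = arena$water_depth_cm)
  if (any(values_cm < 0 | values_cm > extent))
    stop("position outside the [0, ", extent, "] cm axis extent")
  n_bins <- as.integer(ceiling(extent / bin_cm))
  sym <- pmin(as.integer(floor(values_cm / bin_cm)), n_bins - 1L)
  structure(sym, alphabet_size = n_bins, axis = axis)
}

# Map behavior-state labels to integer symbols 0..2.
encode_states <- function(states) {
  sym <- match(states, behavior_states()) - 1L
  if (anyNA(sym)) stop("unknown behavior state label")
  structure(sym, alphabet_size = 3L)
}

alphabet_of <- function(x) {
  a <- attr(x, "alphabet_size")
  if (is.null(a)) max(x) + 1L else a
}

#' Discrete plug-in transfer entropy (bits)
#'
#' The transfer entropy from a source process R to a target process F with
#' history length one,
#' `TE = sum P(F_{t+1}, F_t, R_t) log2 [ P(F_{t+1} | F_t, R_t) / P(F_{t+1} | F_t) ]`,
#' with all probabilities the empirical (plug-in) frequencies of the paired
#' series over `t = 1 .. N-1`. Terms with zero joint probability contribute
#' zero; no pseudo-counts are used. The estimate is a conditional mutual
#' information of the empirical joint distribution, hence nonnegative, and
#' bounded above by `log2` of the target alphabet size.
#'
#' @param source Integer symbol vector (R process), values in
#'   `0 .. alphabet - 1`.
#' @param target Integer symbol vector (F process), same length, aligned in
#'   time with `source`.
#' @return List of class `te_result` with `te_bits`, `n_samples`,
#'   `source_alphabet`, `target_alphabet`.
#' @export
transfer_entropy <- function(source, target) {
  if (length(source) != length(target))
    stop("source and target must have equal length")
  n <- length(source)
  if (n < 2) stop("need at least 2 samples")
  ka <- alphabet_of(source)
  kf <- alphabet_of(target)
  f1 <- target[-1]           # F_{t+1}
  f0 <- target[-n]           # F_t
  r0 <- source[-n]           # R_t
  # joint counts over (F_{t+1}, F_t, R_t) via a single linear index
  idx <- f1 + kf * (f0 + kf * r0)
  c_ffr <- tabulate(idx + 1L, nbins = kf * kf * ka)
  dim(c_ffr) <- c(kf, kf, ka)
  c_fr <- colSums(c_ffr)                       # counts of (F_t, R_t)
  c_ff <- rowSums(c_ffr, dims = 2)             # counts of (F_{t+1}, F_t)
  c_f0 <- colSums(c_ff)                        # counts of F_t
  N <- n - 1
  nz <- which(c_ffr > 0, arr.ind = TRUE)
  cnt <- c_ffr[nz]
  p_cond_fr <- cnt / c_fr[nz[, 2:3, drop = FALSE]]
  p_cond_f <- c_ff[nz[, 1:2, drop = FALSE]] / c_f0[nz[, 2]]
  te <- sum(cnt / N * log2(p_cond_fr / p_cond_f))
  structure(list(te_bits = max(0, te), n_samples = n,
                 source_alphabet = ka, target_alphabet = kf),
            class = "te_result")
}

#' Surrogate-pairing permutation test for mean transfer entropy
#'
#' Tests whether the mean transfer entropy over the true (fish, robot) trial
#' pairings exceeds chance. The null distribution is built by randomly
#' re-pairing the fish series with the robot series (uniform over all
#' permutations, identity included) and recomputing the mean transfer
#' entropy, repeated `n_perm` times. The observed mean is significant when it
#' lies in the right tail, strictly above the 95% quantile of the null (a
#' degenerate null, as with identical series, is never significant).
#'
#' Unequal series lengths within a pair are truncated to the shorter series.
#' Since each permutation only re-pairs whole series, the per-pair transfer
#' entropies for all source x target combinations are precomputed once and
#' each surrogate mean is a lookup.
#'
#' @param fish_series List of target symbol vectors, one per trial.
#' @param robot_series List of source symbol vectors, same number of trials.
#' @param n_perm Number of surrogate permutations; default 1000.
#' @return List of class `surrogate_test` with `observed_mean_te`,
#'   `per_trial_te`, `null_means`, `q05`, `q95`, `significant`.
#' @export
surrogate_test <- function(fish_series, robot_series, n_perm = 1000) {
  m <- length(fish_series)
  if (length(robot_series) != m)
    stop("fish and robot ensembles must have the same number of trials")
  if (m < 2) stop("need at least 2 trials")
  te_pair <- function(r, f) {
    n <- min(length(r), length(f))
    transfer_entropy(r[seq_len(n)], f[seq_len(n)])$te_bits
  }
  te_mat <- matrix(NA_real_, m, m)  # [robot j, fish i]
  for (j in seq_len(m)) for (i in seq_len(m))
    te_mat[j, i] <- te_pair(robot_series[[j]], fish_series[[i]])
  observed <- mean(diag(te_mat))
  null_means <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(m)
    mean(te_mat[cbind(perm, seq_len(m))])
  }, numeric(1))
  q <- stats::quantile(null_means, c(0.05, 0.95), names = FALSE, type = 7)
  structure(list(observed_mean_te = observed,
                 per_trial_te = diag(te_mat),
                 null_means = null_means,
                 q05 = q[1], q95 = q[2],
                 significant = observed > q[2]),
            class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf(
    "Surrogate test: observed mean TE %.4f bits, null 95%% quantile %.4f (%s)\n",
    x$observed_mean_te, x$q95,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Symbolic series for transfer entropy from a trial
#'
#' Extracts the 1 Hz symbol pair (robot behavior states, binned fish
#' position) over the observation window of a trial.
#'
#' @param trial A `trial_record`.
#' @param axis `"depth"` (vertical position) or `"length"` (longitudinal).
#' @return List with `fish` and `robot` integer symbol vectors.
#' @export
trial_te_series <- function(trial, axis = c("depth", "length")) {
  axis <- match.arg(axis)
  fish <- observation_window(trial, trial$fish_traj)
  pos <- switch(axis, depth = fish$z_cm, length = fish$x_cm)
  fish_sym <- bin_position(downsample(pos), axis, trial$arena)
  states <- trial$robot_states[(trial$habituation_s + 1):
                                 (trial$habituation_s + trial$observation_s)]
  list(fish = fish_sym, robot = encode_states(states))
}
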
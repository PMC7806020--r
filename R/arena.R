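#' Arena geometry
#'
#' The experimental tank: a 42 x 30 cm central compartment holding the fish,
#' flanked by a 16 cm lateral compartment holding the robotic replica, with a
#' shared transparent wall. Coordinates are in cm with the origin at the
#' bottom corner of the central tank on the replica side: x runs along the
#' tank length (0 at the replica-side wall, so the replica occupies negative
#' x), y along the width, z upward from the base. The water depth defaults to
#' 15 cm, consistent with a 5 cm bottom section being the bottom third of the
#' water column.
#'
#' @param central_length_cm,central_width_cm Central tank footprint, cm.
#' @param water_depth_cm Water depth, cm.
#' @param lateral_length_cm Length of the replica's lateral tank, cm.
#' @param replica_side `"left"` or `"right"`; bookkeeping only, since the
#'   coordinate frame always puts the replica at negative x.
#' @return A list of class `arena_geometry`.
#' @export
arena_geometry <- function(central_length_cm = 42, central_width_cm = 30,
                           water_depth_cm = 15, lateral_length_cm = 16,
                           replica_side = c("left", "right")) {
  replica_side <- match.arg(replica_side)
  stopifnot(central_length_cm > 0, central_width_cm > 0,
            water_depth_cm > 0, lateral_length_cm > 0)
  structure(list(central_length_cm = central_length_cm,
                 central_width_cm = central_width_cm,
                 water_depth_cm = water_depth_cm,
                 lateral_length_cm = lateral_length_cm,
                 replica_side = replica_side),
            class = "arena_geometry")
}

#' Replica kinematic parameters
#'
#' Movement program of the robotic replica in the lateral tank, per behavior
#' state. Stationary: dive to the bottom and freeze. Swimming: an elliptical
#' orbit in the horizontal plane with axes 2.35 and 10 cm and nominal axis
#' speeds 1.01 and 1.33 cm/s; at each occurrence of a swimming state the
#' y-axis speed is jittered by +/- 0.1 cm/s with probability 0.1 and the
#' replica ascends or dives 1 cm with probability 0.2. Attacking: a constant
#' speed sweep back and forth along the wall adjacent to the central tank.
#'
#' @param ellipse_axis_minor_cm,ellipse_axis_major_cm Full axis lengths of
#'   the swimming ellipse, cm.
#' @param speed_x_cm_s,speed_y_cm_s Nominal axis speeds of the orbit, cm/s.
#' @param speed_jitter_cm_s,speed_jitter_prob Magnitude and per-swim-state
#'   probability of the y-speed perturbation.
#' @param vertical_step_cm,vertical_step_prob Magnitude and per-swim-state
#'   probability of the vertical 1 cm step.
#' @param attack_speed_cm_s Sweep speed while attacking, cm/s.
#' @param descent_speed_cm_s Dive speed toward the bottom while stationary.
#' @param frame_rate_hz Trajectory sampling rate.
#' @return A list of class `robot_kinematics`.
#' @export
robot_kinematics <- function(ellipse_axis_minor_cm = 2.35,
                             ellipse_axis_major_cm = 10,
                             speed_x_cm_s = 1.01, speed_y_cm_s = 1.33,
                             speed_jitter_cm_s = 0.1, speed_jitter_prob = 0.1,
                             vertical_step_cm = 1, vertical_step_prob = 0.2,
                             attack_speed_cm_s = 3,
                             descent_speed_cm_s = 2,
                             frame_rate_hz = 30) {
  stopifnot(speed_jitter_prob >= 0, speed_jitter_prob <= 1,
            vertical_step_prob >= 0, vertical_step_prob <= 1,
            attack_speed_cm_s > 0, descent_speed_cm_s > 0,
            frame_rate_hz >= 1)
  structure(as.list(environment()), class = "robot_kinematics")
}

#' Synthetic fish behavior parameters
#'
#' Parameters of the bounded correlated random walk standing in for the live
#' fish. The walk has a persistent horizontal heading perturbed by Gaussian
#' noise each frame, a fluctuating speed, a mean-reverting vertical drift
#' toward a preferred height, and reflecting walls. `habituation_bias` sets
#' the preferred height during habituation as a fraction of the water depth
#' (low values emulate the initial bottom-dwelling of a fish in a novel
#' tank); during observation the preferred height relaxes to mid-column.
#' When the concurrent replica state is attacking, the fish receives a
#' vertical drift toward the half of the water column opposite the replica,
#' scaled by `gain_vertical`, and a longitudinal drift away from the
#' replica-side third, scaled by `gain_horizontal`. With both gains zero the
#' trajectory law is independent of the replica's state sequence.
#'
#' @param mean_speed_cm_s Mean swim speed, cm/s (about 2 body lengths/s).
#' @param speed_sd_cm_s Standard deviation of per-frame speed fluctuation.
#' @param turning_noise_rad Per-frame SD of the heading increment, rad.
#' @param vertical_drift Mean-reversion rate of z toward the preferred
#'   height, 1/s.
#' @param vertical_noise_cm_s SD of the per-second vertical velocity noise.
#' @param gain_vertical Dimensionless avoidance gain coupling the fish's
#'   vertical drift to the replica's attacking state; 0 disables.
#' @param gain_horizontal Same for the longitudinal axis; 0 disables.
#' @param habituation_bias Preferred height during habituation, as a
#'   fraction of water depth.
#' @return A list of class `fish_params`.
#' @export
fish_params <- function(mean_speed_cm_s = 6, speed_sd_cm_s = 2,
                        turning_noise_rad = 0.35,
                        vertical_drift = 0.4, vertical_noise_cm_s = 1.5,
                        gain_vertical = 1, gain_horizontal = 0,
                        habituation_bias = 0.25) {
  stopifnot(mean_speed_cm_s > 0, gain_vertical >= 0, gain_horizontal >= 0,
            habituation_bias >= 0, habituation_bias <= 1)
  structure(as.list(environment()), class = "fish_params")
}
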
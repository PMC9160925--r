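# Simplified musculoskeletal surrogate: a three-segment rodent forelimb
# (humerus, ulna/radius, foot) with eight muscles — two antagonists per
# actuated rotation axis — and a two-DOF joystick carrying a constant bias
# torque. Deliberately reduced: per-DOF lumped inertia, constant moment
# arms, force-length/velocity factors of one, first-order activation
# dynamics, and a 2-DOF elastic kinematic coupling of the foot onto the
# joystick. All passive elements derive from potentials, so with zero
# excitation the rig is dissipative.

#' Default forelimb-plus-joystick configuration
#'
#' Three moving segments (humerus, ulna/radius, foot), four actuated limb
#' rotation axes (shoulder flexion/abduction, elbow flexion, wrist flexion)
#' with one antagonist muscle pair each (8 muscles total), and a joystick
#' with two revolute DOF (forward/backward, lateral/medial) receiving a
#' constant bias torque of -0.001 Nm. Masses and lengths are documented
#' surrogate constants, not measurements.
#'
#' @param bias_torque_nm joystick bias torque, Nm (default -0.001).
#' @param inner_dt_ms inner integration step, ms (default 1).
#' @return plant configuration of class `embsnn_plant_config`.
#' @export
build_default_forelimb <- function(bias_torque_nm = -0.001,
                                   inner_dt_ms = 1) {
  segments <- data.frame(
    name = c("humerus", "ulna_radius", "foot"),
    mass_kg = c(0.0008, 0.0006, 0.0003),
    length_m = c(0.012, 0.014, 0.008))
  segments$inertia_kgm2 <- segments$mass_kg * segments$length_m^2 / 3
  dof <- c("shoulder_flex", "shoulder_abd", "elbow_flex", "wrist_flex",
           "joy_fb", "joy_lm")
  # lumped rotational inertia per DOF; joystick is a light stick
  inertia <- c(rep(sum(segments$inertia_kgm2), 4), 2e-7, 2e-7)
  damping <- c(rep(5e-4, 4), 1e-4, 1e-4)       # Nm s / rad
  stiffness <- c(rep(2e-3, 4), 5e-3, 5e-3)     # passive elastic, Nm / rad
  # muscles: columns are the 8 muscles, two per actuated axis with
  # opposite-signed constant moment arms
  muscles <- data.frame(
    name = c("sh_flexor", "sh_extensor", "sh_abductor", "sh_adductor",
             "el_flexor", "el_extensor", "wr_flexor", "wr_extensor"),
    axis = rep(1:4, each = 2),
    arm_m = rep(c(0.002, -0.002), 4),
    F_max_N = 1,
    tau_act_s = 0.01,
    tau_deact_s = 0.04)
  # moment-arm matrix R[dof, muscle]
  R <- matrix(0, length(dof), nrow(muscles))
  for (m in seq_len(nrow(muscles))) {
    R[muscles$axis[m], m] <- muscles$arm_m[m]
  }
  # elastic coupling e = C q: foot displacement maps onto joystick DOF
  C <- matrix(0, 2, length(dof),
              dimnames = list(c("fb", "lm"), dof))
  C["fb", "shoulder_flex"] <- 0.5
  C["fb", "elbow_flex"] <- 1
  C["fb", "joy_fb"] <- -1
  C["lm", "shoulder_abd"] <- 0.7
  C["lm", "wrist_flex"] <- 0.5
  C["lm", "joy_lm"] <- -1
  structure(list(segments = segments, dof = dof, inertia = inertia,
                 damping = damping, stiffness = stiffness,
                 muscles = muscles, moment_arms = R,
                 coupling = C, k_coupling = 2e-3,
                 bias_torque_nm = bias_torque_nm,
                 joystick_dof = c(5L, 6L),
                 inner_dt_ms = inner_dt_ms),
            class = "embsnn_plant_config")
}

#' Initial plant state
#' @param config plant configuration.
#' @return state list with joint angles `q` (rad), velocities `qdot`
#'   (rad/s) and muscle activations `a` in [0,1]^8.
#' @export
plant_init <- function(config) {
  list(q = numeric(length(config$dof)),
       qdot = numeric(length(config$dof)),
       a = numeric(nrow(config$muscles)))
}

#' Advance the plant by one inner step
#'
#' First-order activation dynamics `da/dt = (u - a)/tau` (exact exponential
#' update; tau_act when excitation exceeds activation, tau_deact
#' otherwise), constant-moment-arm muscle torques, passive stiffness,
#' elastic joystick coupling, bias torque on the joystick DOF, and
#' semi-implicit Euler integration with implicit damping.
#'
#' @param config plant configuration.
#' @param state state from [plant_init()] or a previous step.
#' @param u muscle excitations, clipped to [0,1]^8.
#' @param dt step width in seconds (defaults to the configured inner step).
#' @return the new state.
#' @export
plant_step <- function(config, state, u = numeric(8),
                       dt = config$inner_dt_ms / 1000) {
  stopifnot(dt > 0)
  if (!all(is.finite(state$q)) || !all(is.finite(state$qdot)) ||
      !all(is.finite(state$a))) {
    stop("non-finite plant state", call. = FALSE)
  }
  u <- pmin(pmax(u, 0), 1)
  mus <- config$muscles
  tau <- ifelse(u > state$a, mus$tau_act_s, mus$tau_deact_s)
  a <- u + (state$a - u) * exp(-dt / tau)
  force <- mus$F_max_N * a
  trq <- as.numeric(config$moment_arms %*% force)
  e <- as.numeric(config$coupling %*% state$q)
  trq <- trq - config$k_coupling * as.numeric(crossprod(config$coupling, e))
  trq <- trq - config$stiffness * state$q
  trq[config$joystick_dof] <- trq[config$joystick_dof] +
    config$bias_torque_nm
  qdot <- (state$qdot + dt * trq / config$inertia) /
    (1 + dt * config$damping / config$inertia)
  q <- state$q + dt * qdot
  list(q = q, qdot = qdot, a = a)
}

#' Advance the plant over a window
#' @param config plant configuration.
#' @param state current state.
#' @param u excitations held constant over the window.
#' @param window_ms window length in ms; subdivided into inner steps.
#' @return the state after the window.
#' @export
plant_advance <- function(config, state, u, window_ms) {
  n <- max(1L, as.integer(round(window_ms / config$inner_dt_ms)))
  dt <- window_ms / n / 1000
  for (i in seq_len(n)) state <- plant_step(config, state, u, dt)
  state
}

#' Joystick angles
#'
#' @param state plant state.
#' @return named vector (forward/backward, lateral/medial) in rad; positive
#'   means forward / lateral.
#' @export
joystick_angles <- function(state) {
  c(fb = state$q[5], lm = state$q[6])
}

#' Total mechanical energy of the plant
#'
#' Kinetic energy plus the passive potentials (joint stiffness, coupling
#' spring, joystick bias). With zero excitation this quantity is
#' non-increasing along trajectories: damping is the only non-potential
#' force.
#'
#' @param config plant configuration.
#' @param state plant state.
#' @return energy in J.
#' @export
plant_energy <- function(config, state) {
  e <- as.numeric(config$coupling %*% state$q)
  sum(0.5 * config$inertia * state$qdot^2) +
    sum(0.5 * config$stiffness * state$q^2) +
    0.5 * config$k_coupling * sum(e^2) -
    config$bias_torque_nm * sum(state$q[config$joystick_dof])
}

#' Write a plant trajectory log
#' @param log data.frame with t and state columns.
#' @param path CSV path.
#' @export
write_trajectory <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
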